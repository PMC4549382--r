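#' Streamline visitation map
#'
#' Per-voxel count of streamlines traversing each voxel: every streamline
#' increments a voxel at most once, regardless of how many of its points
#' fall inside. A voxel counts as traversed when any streamline point lies
#' in it (with tracking steps much smaller than the voxel size this
#' approximates exact segment-voxel intersection). The support mask is the
#' union of traversed voxels.
#'
#' @param streamlines List of point matrices (or a \code{tractogram}).
#' @param dims Volume dimensions.
#' @param voxel_mm Isotropic voxel size (mm).
#' @return An object of class \code{visitation_map}: \code{counts} (3D
#'   array) and \code{support} (logical 3D array).
#' @export
visitation_map <- function(streamlines, dims = NULL, voxel_mm = NULL) {
  if (inherits(streamlines, "tractogram")) {
    if (is.null(dims)) dims <- streamlines$dims
    if (is.null(voxel_mm)) voxel_mm <- streamlines$voxel_mm
    streamlines <- streamlines$streamlines
  }
  counts <- array(0L, dims)
  for (m in streamlines) {
    vox <- unique(points_to_flat_voxels(m, voxel_mm, dims))
    vox <- vox[!is.na(vox)]
    counts[vox] <- counts[vox] + 1L
  }
  structure(list(counts = counts, support = counts >= 1L,
                 dims = dims, voxel_mm = voxel_mm),
            class = "visitation_map")
}

#' Mean FA and MD over a segment's visitation support
#'
#' Unweighted mean of each scalar map over the voxels traversed by the
#' segment's streamlines.
#'
#' @param vmap A \code{visitation_map}.
#' @param fa_map,md_map \code{scalar_map}s on the same grid.
#' @return Named numeric vector \code{c(fa = ..., md = ...)}.
#' @export
segment_mean_scalars <- function(vmap, fa_map, md_map) {
  if (!any(vmap$support)) stop("empty visitation support")
  c(fa = mean(fa_map$values[vmap$support], na.rm = TRUE),
    md = mean(md_map$values[vmap$support], na.rm = TRUE))
}

#' Paired t test
#'
#' Classical paired t on the within-pair differences (two-sided), df = n-1.
#'
#' @param a,b Paired samples of equal length (n >= 2).
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("paired samples must have equal length >= 2")
  if (stats::sd(a - b) == 0)
    stop("degenerate: zero-variance differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Bonferroni correction
#'
#' \code{min(1, p * m)} elementwise for a family of \code{m} comparisons.
#'
#' @param p Probabilities in [0, 1].
#' @param m Family size (>= number of p values).
#' @return Corrected probabilities.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1, m >= length(p))
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject ANOVA for a complete balanced design with one observation
#' per subject and cell. Sums of squares are partitioned with subject as a
#' blocking factor and each within-subject effect is tested against its own
#' subject-by-effect error stratum (the univariate repeated-measures F,
#' without sphericity correction).
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector of the two within-subject factor columns.
#' @return Data frame with one row per effect (two main effects and the
#'   interaction): \code{effect, df_effect, df_error, F, p}; the full
#'   sums-of-squares partition is attached as attribute \code{"ss"}.
#' @export
rm_anova <- function(data, dv, subject = "subject",
                     within = c("segment", "hemisphere")) {
  stopifnot(length(within) == 2)
  d <- data.frame(y = data[[dv]],
                  subject = factor(data[[subject]]),
                  A = factor(data[[within[1]]]),
                  B = factor(data[[within[2]]]))
  tab <- table(d$subject, d$A, d$B)
  if (any(tab != 1))
    stop("incomplete design: every subject needs exactly one observation per cell")
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tabs <- sm[[paste0("Error: ", stratum)]][[1]]
    rn <- trimws(rownames(tabs))
    i <- match(term, rn)
    j <- match("Residuals", rn)
    data.frame(effect = term,
               df_effect = tabs$Df[i], df_error = tabs$Df[j],
               F = tabs$`F value`[i], p = tabs$`Pr(>F)`[i])
  }
  out <- rbind(pull("subject:A", "A"), pull("subject:B", "B"),
               pull("subject:A:B", "A:B"))
  out$effect <- c(within, paste(within, collapse = ":"))
  # SS partition: effects + subject + the pooled within-subject error strata
  ss_term <- function(stratum, term) {
    tabs <- sm[[paste0("Error: ", stratum)]][[1]]
    tabs$`Sum Sq`[match(term, trimws(rownames(tabs)))]
  }
  ss <- list(subject = ss_term("subject", "Residuals"),
             A = ss_term("subject:A", "A"),
             B = ss_term("subject:B", "B"),
             AB = ss_term("subject:A:B", "A:B"),
             error = ss_term("subject:A", "Residuals") +
               ss_term("subject:B", "Residuals") +
               ss_term("subject:A:B", "Residuals"),
             total = sum((d$y - mean(d$y))^2))
  names(ss)[2:4] <- c(within, paste(within, collapse = ":"))
  # a zero-variance effect has F = 0 by definition (0/0 in the aov table,
  # which numerical fuzz can otherwise turn into an arbitrary ratio)
  zero_eff <- unlist(ss[2:4]) <= 1e-10 * max(ss$total, sum(d$y^2),
                                             .Machine$double.xmin)
  out$F[zero_eff] <- 0
  out$p[zero_eff] <- 1
  attr(out, "ss") <- ss
  rownames(out) <- NULL
  out
}
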