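#' Flat cortical sheet geometry
#'
#' A regular lattice stand-in for a cortical surface patch: vertex positions
#' in mm, a per-vertex area, and the lattice dimensions. Rows of the lattice
#' run along the visual-area band axis (the direction in which polar angle
#' progresses and reverses); columns run along the eccentricity axis.
#'
#' @param n_band Number of rows (band axis).
#' @param n_ecc Number of columns (eccentricity axis).
#' @param spacing_mm Vertex spacing (mm); per-vertex area is
#'   \code{spacing_mm^2}.
#' @return An object of class \code{sheet_geometry} with fields \code{pos}
#'   (V x 2 mm), \code{area} (mm^2 per vertex), \code{n_band}, \code{n_ecc},
#'   \code{spacing_mm}.
#' @export
sheet_geometry <- function(n_band, n_ecc, spacing_mm = 1) {
  stopifnot(n_band >= 2, n_ecc >= 1, spacing_mm > 0)
  idx <- expand.grid(band = seq_len(n_band), ecc = seq_len(n_ecc))
  structure(list(pos = cbind((idx$band - 1) * spacing_mm,
                             (idx$ecc - 1) * spacing_mm),
                 area = rep(spacing_mm^2, n_band * n_ecc),
                 n_band = as.integer(n_band), n_ecc = as.integer(n_ecc),
                 spacing_mm = spacing_mm),
            class = "sheet_geometry")
}

# vertex index for (band row, ecc column) in the column-major sheet layout
sheet_index <- function(sheet, band, ecc) (ecc - 1L) * sheet$n_band + band

#' Visual-area label levels
#'
#' The six retinotopic regions (dorsal/ventral halves of V1-V3), the V3A
#' control region, and \code{"none"}.
#' @return Character vector of label levels.
#' @export
visual_area_levels <- function() {
  c("V1d", "V1v", "V2d", "V2v", "V3d", "V3v", "V3A", "none")
}

# local extrema of a 1D profile: interior points where the discrete
# derivative changes sign, filtered by prominence against both neighbors
profile_extrema <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  cand <- which(d[-length(d)] * d[-1] < 0) + 1L
  keep <- vapply(cand, function(i) {
    left <- abs(x[i] - x[1:(i - 1)])
    right <- abs(x[i] - x[(i + 1):n])
    max(left) >= min_prominence && max(right) >= min_prominence
  }, logical(1))
  cand[keep]
}

#' Delineate visual areas from a polar-angle map
#'
#' Automates the classical delineation of early visual areas on a flat
#' sheet: polar angle is averaged along iso-eccentricity lines to a 1D
#' profile over the band axis, boundaries are placed at the polar-angle
#' reversals (local extrema of the profile), V1 is identified as the band
#' spanning the largest polar-angle range (a full hemifield with no internal
#' reversal), and bands are labeled outward from V1 as V2 and V3 on each
#' side, with the band beyond dorsal V3 labeled V3A. V1 is split into dorsal
#' and ventral halves at the horizontal-meridian representation (sign of the
#' pRF-center vertical coordinate).
#'
#' @param polar_map Per-vertex polar angle (degrees, \code{atan2(y0, x0)}
#'   convention: positive = upper visual field).
#' @param ecc_map Per-vertex eccentricity (degrees); currently used only for
#'   validity checks, the lattice provides the iso-eccentricity direction.
#' @param sheet A \code{sheet_geometry}.
#' @param min_prominence Minimum polar-angle excursion (degrees) for a
#'   reversal to count as a boundary; guards against noise wiggles.
#' @return Factor of per-vertex labels (levels
#'   \code{\link{visual_area_levels}}) with attribute
#'   \code{"boundaries"} (band-row indices of the detected reversals).
#' @export
delineate_areas <- function(polar_map, ecc_map, sheet, min_prominence = 30) {
  V <- sheet$n_band * sheet$n_ecc
  stopifnot(length(polar_map) == V, length(ecc_map) == V)
  pm <- matrix(polar_map, sheet$n_band, sheet$n_ecc)
  profile <- rowMeans(pm, na.rm = TRUE)
  if (any(!is.finite(profile)))
    stop("delineation failure: non-finite polar-angle profile")
  ext <- profile_extrema(profile, min_prominence)
  if (length(ext) == 0)
    stop("delineation failure: no polar-angle reversals detected")

  # bands between consecutive reversals (sheet edges close the outer bands);
  # a reversal row is assigned to the band it terminates
  edges <- c(0L, ext, sheet$n_band)
  n_bands <- length(edges) - 1L
  band_of_row <- integer(sheet$n_band)
  for (b in seq_len(n_bands))
    band_of_row[(edges[b] + 1L):edges[b + 1L]] <- b

  rng <- vapply(seq_len(n_bands), function(b)
    diff(range(profile[band_of_row == b])), numeric(1))
  v1 <- which.max(rng)

  band_label <- rep("none", n_bands)
  band_label[v1] <- "V1"
  # ventral side = neighbor band representing the upper field (positive angle)
  mean_angle <- vapply(seq_len(n_bands), function(b)
    mean(profile[band_of_row == b]), numeric(1))
  ventral_side <- if (v1 > 1 && mean_angle[v1 - 1] > 0) -1L else 1L
  ventral_order <- c("V2v", "V3v")
  dorsal_order <- c("V2d", "V3d", "V3A")
  for (i in seq_along(ventral_order)) {
    b <- v1 + ventral_side * i
    if (b >= 1 && b <= n_bands) band_label[b] <- ventral_order[i]
  }
  for (i in seq_along(dorsal_order)) {
    b <- v1 - ventral_side * i
    if (b >= 1 && b <= n_bands) band_label[b] <- dorsal_order[i]
  }

  row_label <- band_label[band_of_row]
  # split V1 at the horizontal-meridian representation
  v1_rows <- which(row_label == "V1")
  row_label[v1_rows] <- ifelse(profile[v1_rows] >= 0, "V1v", "V1d")

  labels <- factor(rep(row_label, times = sheet$n_ecc),
                   levels = visual_area_levels())
  attr(labels, "boundaries") <- ext
  labels
}

#' Surface area of each labeled region
#'
#' @param labels Per-vertex labels (factor or character using
#'   \code{\link{visual_area_levels}}).
#' @param sheet A \code{sheet_geometry} aligned with the labels.
#' @return Named numeric vector of areas (mm^2), one entry per region label
#'   present (excluding \code{"none"}).
#' @export
region_surface_area <- function(labels, sheet) {
  labels <- as.character(labels)
  if (length(labels) != length(sheet$area))
    stop("labels and sheet are not aligned")
  known <- visual_area_levels()
  if (any(!labels %in% known)) stop("unknown region label")
  keep <- labels != "none"
  out <- tapply(sheet$area[keep], labels[keep], sum)
  stats::setNames(as.numeric(out), names(out))
}
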