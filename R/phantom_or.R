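#' Configuration of the optic-radiation tensor phantom
#'
#' Six prolate fiber bundles (V1/V2/V3 crossed with dorsal/ventral) run
#' from an LGN-analogue seed region posteriorly to cortical target blocks,
#' following C-shaped (laterally bowed) centerlines with the
#' medio-lateral V1 < V2 < V3 nesting and a superior-inferior
#' dorsal/ventral split. An isotropic high-diffusivity CSF slab (the
#' posterior-horn analogue) lies beneath the ventral route and bleeds
#' partial volume into the adjacent ventral bundle voxels; a V3A target
#' block receives no bundle. Eigenvalues default to typical literature
#' magnitudes: bundle (1.7, 0.2, 0.2), background (0.8, 0.7, 0.7), CSF
#' (3.0, 3.0, 3.0), all 1e-3 mm^2/s.
#'
#' @param dims Volume dimensions (voxels).
#' @param voxel_mm Isotropic voxel size (mm).
#' @param bundle_evals,background_evals,csf_evals Eigenvalue triples
#'   (mm^2/s).
#' @param bundle_radius_mm Tube radius of each bundle (mm).
#' @param bow_mm Lateral bow amplitude of the C-shaped centerlines (mm).
#' @param csf_blend_w Partial-volume weight of CSF mixed into bundle voxels
#'   adjacent to the slab (0 disables).
#' @param seed Random seed recorded for downstream simulation.
#' @return An object of class \code{or_phantom_config}.
#' @export
or_phantom_config <- function(dims = c(40L, 50L, 40L), voxel_mm = 1,
                              bundle_evals = c(1.7, 0.2, 0.2) * 1e-3,
                              background_evals = c(0.8, 0.7, 0.7) * 1e-3,
                              csf_evals = c(3.0, 3.0, 3.0) * 1e-3,
                              bundle_radius_mm = 1.45, bow_mm = 5,
                              csf_blend_w = 0.3, seed = 1L) {
  stopifnot(all(dims >= 16), voxel_mm > 0, bundle_radius_mm > 0,
            csf_blend_w >= 0, csf_blend_w <= 1)
  structure(list(dims = as.integer(dims), voxel_mm = voxel_mm,
                 bundle_evals = bundle_evals,
                 background_evals = background_evals,
                 csf_evals = csf_evals,
                 bundle_radius_mm = bundle_radius_mm, bow_mm = bow_mm,
                 csf_blend_w = csf_blend_w, seed = as.integer(seed)),
            class = "or_phantom_config")
}

# bundle lane geometry shared by the phantom and the labeled tractogram:
# start/end lateral (x) and vertical (z) lanes per area x dorsal/ventral
or_bundle_plan <- function() {
  plan <- expand.grid(area = c("V1", "V2", "V3"), dv = c("d", "v"),
                      stringsAsFactors = FALSE)
  plan$label <- paste0(plan$area, plan$dv)
  a <- match(plan$area, c("V1", "V2", "V3"))
  plan$x_start <- 10 + (a - 2) * 4
  plan$x_end <- c(8, 14, 20)[a]
  plan$z_start <- ifelse(plan$dv == "d", 23, 17)
  plan$z_end <- ifelse(plan$dv == "d", 26, 14)
  plan$y_start <- 10
  plan$y_end <- 45
  plan
}

# C-shaped centerline of one bundle, sampled at n points with tangents
or_centerline <- function(row, bow_mm, n = 300) {
  t <- seq(0, 1, length.out = n)
  ss <- 3 * t^2 - 2 * t^3
  x <- row$x_start + (row$x_end - row$x_start) * ss + bow_mm * sin(pi * t)
  y <- row$y_start + (row$y_end - row$y_start) * t
  z <- row$z_start + (row$z_end - row$z_start) * ss
  pts <- cbind(x, y, z)
  tang <- rbind(pts[2, ] - pts[1, ], pts[-1, ] - pts[-n, ])
  tang <- tang / sqrt(rowSums(tang^2))
  list(points = pts, tangents = tang)
}

#' Build the optic-radiation tensor phantom
#'
#' @param cfg An \code{or_phantom_config}.
#' @return List with \code{field} (\code{tensor_field}), \code{fa} and
#'   \code{md} (\code{scalar_map}s), \code{seed_mask}, \code{label_vol}
#'   (integer array indexing \code{\link{visual_area_levels}}),
#'   \code{target_mask}, \code{csf_mask}, \code{bundle_id} (integer array,
#'   0 = none), \code{bundle_labels} (names of the bundle ids),
#'   \code{blended} (logical array of partial-volume voxels), \code{anat}
#'   (an \code{anatomy_model}) and \code{cfg}.
#' @export
make_or_phantom <- function(cfg = or_phantom_config()) {
  dims <- cfg$dims
  vs <- cfg$voxel_mm
  plan <- or_bundle_plan()
  lines <- lapply(seq_len(nrow(plan)), function(i)
    or_centerline(plan[i, ], cfg$bow_mm))

  # tubes must not intersect
  r <- cfg$bundle_radius_mm
  for (i in seq_len(length(lines) - 1)) {
    for (j in (i + 1):length(lines)) {
      dmin <- min(sqrt(outer(rowSums(lines[[i]]$points^2), rep(1, 300)) +
                         outer(rep(1, 300), rowSums(lines[[j]]$points^2)) -
                         2 * lines[[i]]$points %*% t(lines[[j]]$points)))
      if (is.finite(dmin) && dmin < 2 * r)
        stop("overlapping bundles: centerlines ", i, " and ", j,
             " come within ", round(dmin, 2), " mm")
    }
  }

  nvox <- prod(dims)
  mindist <- array(Inf, dims)
  bundle_id <- array(0L, dims)
  tang <- matrix(0, nvox, 3)
  reach <- r + vs  # update neighborhood half-width around each sample
  for (b in seq_along(lines)) {
    P <- lines[[b]]$points
    Tg <- lines[[b]]$tangents
    for (s in seq_len(nrow(P))) {
      p <- P[s, ]
      lo <- pmax(1L, as.integer(floor((p - reach) / vs)) + 1L)
      hi <- pmin(dims, as.integer(ceiling((p + reach) / vs)))
      if (any(lo > hi)) next
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
      ctr <- (box - 0.5) * vs
      d <- sqrt((ctr[, 1] - p[1])^2 + (ctr[, 2] - p[2])^2 +
                  (ctr[, 3] - p[3])^2)
      flat <- box[, 1] + dims[1] * (box[, 2] - 1L + dims[2] * (box[, 3] - 1L))
      upd <- d < mindist[flat]
      if (any(upd)) {
        f <- flat[upd]
        mindist[f] <- d[upd]
        bundle_id[f] <- b
        tang[f, ] <- matrix(Tg[s, ], sum(upd), 3, byrow = TRUE)
      }
    }
  }
  in_bundle <- mindist <= r
  bundle_id[!in_bundle] <- 0L

  # CSF slab under the ventral route (posterior-horn analogue)
  idx <- arrayInd(seq_len(nvox), dims)
  ctr_x <- (idx[, 1] - 0.5) * vs
  ctr_y <- (idx[, 2] - 0.5) * vs
  ctr_z <- (idx[, 3] - 0.5) * vs
  csf_mask <- array(ctr_x >= 4 & ctr_x <= 24 & ctr_y >= 26 & ctr_y <= 40 &
                      ctr_z >= 11 & ctr_z <= 13 & bundle_id == 0L, dims)

  # tensors: background everywhere, prolate along the tangent in bundles,
  # isotropic CSF in the slab, partial-volume blend in adjacent bundle voxels
  ev_b <- cfg$bundle_evals
  ev_bg <- cfg$background_evals
  ev_csf <- cfg$csf_evals
  D <- matrix(0, nvox, 6)
  D[, 1] <- ev_bg[1]; D[, 2] <- ev_bg[2]; D[, 3] <- ev_bg[3]
  bi <- which(in_bundle)
  tt <- tang[bi, , drop = FALSE]
  D[bi, 1] <- ev_b[2] + (ev_b[1] - ev_b[2]) * tt[, 1]^2
  D[bi, 2] <- ev_b[2] + (ev_b[1] - ev_b[2]) * tt[, 2]^2
  D[bi, 3] <- ev_b[2] + (ev_b[1] - ev_b[2]) * tt[, 3]^2
  D[bi, 4] <- (ev_b[1] - ev_b[2]) * tt[, 1] * tt[, 2]
  D[bi, 5] <- (ev_b[1] - ev_b[2]) * tt[, 1] * tt[, 3]
  D[bi, 6] <- (ev_b[1] - ev_b[2]) * tt[, 2] * tt[, 3]
  ci <- which(csf_mask)
  D[ci, 1:3] <- ev_csf[1]
  D[ci, 4:6] <- 0

  near_csf <- dilate_mask(csf_mask)
  blended <- array(in_bundle & near_csf, dims)
  if (cfg$csf_blend_w > 0 && any(blended)) {
    w <- cfg$csf_blend_w
    bl <- which(blended)
    D[bl, 1:3] <- (1 - w) * D[bl, 1:3] + w * ev_csf[1]
    D[bl, 4:6] <- (1 - w) * D[bl, 4:6]
  }

  field <- structure(list(D = D, S0 = rep(1, nvox), dims = dims,
                          voxel_mm = vs), class = "tensor_field")
  maps <- tensor_scalar_maps(field)

  seed_mask <- array(in_bundle & ctr_y < 13, dims)

  # cortical target blocks at the bundle ends, plus the V3A control block
  lv <- visual_area_levels()
  label_vol <- array(0L, dims)
  block <- function(x0, z0) {
    ctr_y >= 42 & ctr_y <= 47 & abs(ctr_x - x0) <= 2 & abs(ctr_z - z0) <= 2
  }
  for (b in seq_len(nrow(plan))) {
    sel <- block(plan$x_end[b], plan$z_end[b])
    label_vol[sel] <- match(plan$label[b], lv)
  }
  label_vol[block(26, 26)] <- match("V3A", lv)
  target_mask <- array(label_vol > 0L, dims)

  wall <- array(csf_mask & ctr_z >= 12, dims)  # top layer of the slab
  anat <- anatomy_model(lgn_mm = c(10, 10, 20), midsagittal_x = 0,
                        temporal_plane_y = 4, ventricle_mask = wall,
                        ventricle_normal = c(0, 0, 1), voxel_mm = vs,
                        dims = dims)

  list(field = field, fa = maps$fa, md = maps$md, seed_mask = seed_mask,
       label_vol = label_vol, target_mask = target_mask,
       csf_mask = csf_mask, bundle_id = bundle_id,
       bundle_labels = plan$label, blended = blended, anat = anat,
       cfg = cfg, centerlines = lines)
}

#' Configuration of the labeled synthetic tractogram
#'
#' @param n_per_label Named counts of accepted streamlines per termination
#'   label (names from \code{\link{visual_area_levels}}).
#' @param n_violations Named counts of planted rule violations
#'   (\code{a, b, c, d}).
#' @param jitter_mm Gaussian jitter applied to streamline endpoints (mm).
#' @param step_mm Resampling step (mm).
#' @param seed Random seed.
#' @return An object of class \code{labeled_tractogram_config}.
#' @export
labeled_tractogram_config <- function(n_per_label = c(V1d = 10, V1v = 10,
                                                      V2d = 8, V2v = 8,
                                                      V3d = 6, V3v = 6),
                                      n_violations = c(a = 5, b = 5,
                                                       c = 5, d = 5),
                                      jitter_mm = 0.2, step_mm = 0.2,
                                      seed = 1L) {
  stopifnot(all(n_per_label >= 0), all(n_violations >= 0), jitter_mm >= 0,
            step_mm > 0)
  structure(list(n_per_label = n_per_label, n_violations = n_violations,
                 jitter_mm = jitter_mm, step_mm = step_mm,
                 seed = as.integer(seed)),
            class = "labeled_tractogram_config")
}

#' Generate a tractogram with known labels and planted rule violations
#'
#' Accepted streamlines run from the LGN-analogue to the target block of
#' their termination label; violators are constructed to trigger exactly
#' one rejection heuristic each (a: crossing the midsagittal plane, b:
#' rising superiorly from the LGN, c: plunging antero-inferiorly toward the
#' temporal pole, d: running parallel to the ventricle medial wall). All
#' streamlines are resampled to exact \code{step_mm} spacing.
#'
#' @param cfg A \code{labeled_tractogram_config}.
#' @param phantom Optional OR phantom (from \code{\link{make_or_phantom}})
#'   supplying the anatomy and target geometry; built with defaults when
#'   missing.
#' @return List with \code{tractogram}, \code{truth} (data frame with
#'   columns \code{label} — the intended termination label or \code{""} —
#'   and \code{code} — the planted rejection code or \code{"none"}) and
#'   \code{anat}.
#' @export
make_labeled_tractogram <- function(cfg = labeled_tractogram_config(),
                                    phantom = NULL) {
  if (is.null(phantom)) phantom <- make_or_phantom()
  anat <- phantom$anat
  plan <- or_bundle_plan()
  set.seed(cfg$seed)
  jit <- function(p) p + stats::rnorm(3, sd = cfg$jitter_mm)
  lines <- list()
  truth <- data.frame(label = character(0), code = character(0))
  add <- function(pts, label, code) {
    lines[[length(lines) + 1]] <<- resample_polyline(pts, cfg$step_mm)
    truth[nrow(truth) + 1, ] <<- c(label, code)
  }
  lgn <- anat$lgn_mm
  for (lab in names(cfg$n_per_label)) {
    row <- plan[plan$label == lab, ]
    if (nrow(row) == 0) next
    target <- c(row$x_end, 44.5, row$z_end)
    mid <- c((lgn[1] + row$x_end) / 2 + 3, 28, (lgn[3] + row$z_end) / 2)
    for (i in seq_len(cfg$n_per_label[[lab]]))
      add(rbind(jit(lgn + c(0, 1, 0)), jit(mid), jit(target)), lab, "none")
  }
  viol_paths <- list(
    a = rbind(lgn, c(-5, lgn[2], lgn[3])),
    b = rbind(lgn, c(lgn[1], lgn[2], lgn[3] + 15)),
    c = rbind(lgn, c(lgn[1], 2, lgn[3] - 8)),
    d = rbind(c(15, 20, 13.2), c(15, 40, 13.2)))
  for (code in names(cfg$n_violations)) {
    for (i in seq_len(cfg$n_violations[[code]])) {
      p <- viol_paths[[code]]
      p[nrow(p), ] <- jit(p[nrow(p), ])
      add(p, "", code)
    }
  }
  t <- new_tractogram(lines, seed_voxel = rep(NA_integer_, length(lines)),
                      substream_seed = rep(NA_integer_, length(lines)),
                      params = tracking_params(step_mm = cfg$step_mm),
                      voxel_mm = phantom$cfg$voxel_mm,
                      dims = phantom$cfg$dims)
  list(tractogram = t, truth = truth, anat = anat)
}
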