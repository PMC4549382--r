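#' Probabilistic tracking parameters
#'
#' Defaults follow the seed-to-target protocol used throughout the package:
#' 0.2 mm steps, FA stopping threshold 0.1, 10,000 streamlines, and a
#' curvature constraint expressed as a minimum radius of curvature of 1 mm
#' (the maximum turning angle per step is
#' \code{2 * asin(step / (2 * radius))}).
#'
#' @param step_mm Step size (mm, > 0).
#' @param fa_threshold FA stopping threshold in [0, 1).
#' @param curvature_radius_mm Minimum radius of curvature (mm).
#' @param n_streamlines Number of streamlines to generate.
#' @param max_length_mm Maximum propagation length per direction (mm).
#' @param dispersion Direction-dispersion parameter: the sampled step
#'   direction perturbs the local principal eigenvector with Gaussian sd
#'   \code{dispersion * (1 - FA)} before renormalization, so sampling is
#'   sharper where FA is high; 0 gives deterministic eigenvector tracking.
#' @return An object of class \code{tracking_params}.
#' @export
tracking_params <- function(step_mm = 0.2, fa_threshold = 0.1,
                            curvature_radius_mm = 1, n_streamlines = 10000,
                            max_length_mm = 200, dispersion = 0.25) {
  stopifnot(step_mm > 0, fa_threshold >= 0, fa_threshold < 1,
            curvature_radius_mm > 0, n_streamlines >= 1,
            max_length_mm > 0, dispersion >= 0)
  max_angle <- 2 * asin(min(1, step_mm / (2 * curvature_radius_mm)))
  structure(list(step_mm = step_mm, fa_threshold = fa_threshold,
                 curvature_radius_mm = curvature_radius_mm,
                 max_angle_rad = max_angle,
                 n_streamlines = as.integer(n_streamlines),
                 max_length_mm = max_length_mm, dispersion = dispersion),
            class = "tracking_params")
}

new_tractogram <- function(streamlines, seed_voxel, substream_seed, params,
                           voxel_mm, dims) {
  structure(list(streamlines = streamlines, seed_voxel = seed_voxel,
                 substream_seed = substream_seed, params = params,
                 voxel_mm = voxel_mm, dims = dims),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("Tractogram: %d streamlines, %d-%d points (median %d)\n",
              length(x$streamlines), min(npts), max(npts),
              as.integer(stats::median(npts))))
  invisible(x)
}

#' Number of streamlines in a tractogram
#' @param t A \code{tractogram}.
#' @return Integer count.
#' @export
n_streamlines <- function(t) length(t$streamlines)

#' Endpoints of every streamline
#' @param t A \code{tractogram}.
#' @return n x 6 matrix: first point (columns 1-3) and last point (4-6), mm.
#' @export
streamline_endpoints <- function(t) {
  t(vapply(t$streamlines,
           function(m) c(m[1, ], m[nrow(m), ]), numeric(6)))
}

# world mm -> 1-based voxel index triplet (NA outside the volume)
world_to_voxel <- function(p, voxel_mm, dims) {
  v <- floor(p / voxel_mm) + 1
  if (any(v < 1) || any(v > dims)) return(rep(NA_integer_, 3))
  as.integer(v)
}

# rows of world points -> flat 1-based voxel indices (NA outside)
points_to_flat_voxels <- function(pts, voxel_mm, dims) {
  i <- floor(pts[, 1] / voxel_mm)
  j <- floor(pts[, 2] / voxel_mm)
  k <- floor(pts[, 3] / voxel_mm)
  ok <- i >= 0 & j >= 0 & k >= 0 & i < dims[1] & j < dims[2] & k < dims[3]
  out <- rep(NA_integer_, nrow(pts))
  out[ok] <- as.integer(i[ok] + dims[1] * (j[ok] + dims[2] * k[ok]) + 1)
  out
}

#' Seed-to-target probabilistic streamline tractography
#'
#' Seeds are drawn uniformly from the seed ROI (uniform over its voxels,
#' then uniform within the voxel). From each seed the streamline is
#' propagated bidirectionally in steps of \code{step_mm} along directions
#' sampled about the local principal eigenvector (sign-aligned with the
#' previous step), and terminates on FA below threshold, on leaving the
#' volume, on exceeding the curvature constraint, or at the maximum length.
#' One master seed drives everything; each streamline runs on its own
#' counter-indexed RNG substream, so any subset of streamlines is
#' reproducible.
#'
#' @param field A \code{tensor_field}.
#' @param fa_map \code{scalar_map} of FA on the same grid (recomputed from
#'   the field when \code{NULL}).
#' @param seed_roi Logical 3D array marking seed voxels.
#' @param params A \code{tracking_params}.
#' @param seed Master random seed (integer).
#' @return A \code{tractogram}.
#' @export
track <- function(field, fa_map = NULL, seed_roi, params = tracking_params(),
                  seed = 1L) {
  if (is.null(fa_map)) fa_map <- tensor_scalar_maps(field)$fa
  if (!any(seed_roi)) stop("empty seed ROI")
  stopifnot(all(dim(seed_roi) == field$dims))
  e <- tensor_eigen(field)
  n <- params$n_streamlines
  vox_idx <- which(seed_roi)
  set.seed(seed)
  pick <- vox_idx[sample.int(length(vox_idx), n, replace = TRUE)]
  ijk <- arrayInd(pick, dim(seed_roi)) - 1L
  offs <- matrix(stats::runif(3 * n), n, 3)
  seeds <- (ijk + offs) * field$voxel_mm
  substreams <- sample.int(.Machine$integer.max, n, replace = TRUE)
  sl <- track_streamlines_cpp(e$e1, as.numeric(fa_map$values),
                              as.integer(field$dims), field$voxel_mm,
                              seeds, as.numeric(substreams),
                              params$step_mm, params$fa_threshold,
                              params$max_angle_rad, params$dispersion,
                              as.integer(round(params$max_length_mm /
                                                 params$step_mm)))
  new_tractogram(sl, pick, substreams, params, field$voxel_mm, field$dims)
}

#' Subset a tractogram
#'
#' @param t A \code{tractogram}.
#' @param keep Logical or integer index over streamlines.
#' @return The subsetted \code{tractogram}.
#' @export
subset_tractogram <- function(t, keep) {
  new_tractogram(t$streamlines[keep], t$seed_voxel[keep],
                 t$substream_seed[keep], t$params, t$voxel_mm, t$dims)
}

#' Retain streamlines terminating in a target mask
#'
#' A streamline is kept when at least one endpoint lies inside the target
#' mask; membership is decided by the voxel containing the endpoint.
#'
#' @param t A \code{tractogram}.
#' @param target Logical 3D array on the tracking grid.
#' @return The filtered \code{tractogram}.
#' @export
retain_target_terminating <- function(t, target) {
  stopifnot(all(dim(target) == t$dims))
  ep <- streamline_endpoints(t)
  inmask <- function(p) {
    v <- points_to_flat_voxels(matrix(p, 1, 3), t$voxel_mm, t$dims)
    !is.na(v) && target[v]
  }
  keep <- vapply(seq_len(nrow(ep)), function(i)
    inmask(ep[i, 1:3]) || inmask(ep[i, 4:6]), logical(1))
  subset_tractogram(t, keep)
}

#' Resample a polyline at fixed arc-length spacing
#'
#' Linear interpolation along the cumulative arc length at exact multiples
#' of \code{step_mm}; any sub-step remainder at the end is dropped, so all
#' consecutive points are exactly \code{step_mm} apart.
#'
#' @param points n x 3 matrix of ordered points (mm).
#' @param step_mm Target spacing (mm).
#' @return Matrix of resampled points.
#' @export
resample_polyline <- function(points, step_mm) {
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- seq(0, total, by = step_mm)
  out <- matrix(NA_real_, length(targets), 3)
  for (d in 1:3)
    out[, d] <- stats::approx(s, points[, d], xout = targets, ties = "ordered")$y
  out
}
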