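#' Diffusion gradient table
#'
#' @param bvals Numeric b-values (s/mm^2), one per volume.
#' @param bvecs N x 3 matrix of gradient directions (unit vectors for
#'   nonzero-b entries; the b = 0 rows may be zero).
#' @return An object of class \code{gradient_table}.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  stopifnot(length(bvals) == nrow(bvecs), ncol(bvecs) == 3)
  if (!any(bvals == 0)) stop("gradient table needs at least one b = 0 entry")
  nz <- bvals > 0
  if (sum(nz) < 6) stop("at least 6 nonzero-b directions are required")
  # non-collinearity check: the 6 quadratic forms must span rank 6
  g <- bvecs[nz, , drop = FALSE]
  Q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  if (qr(Q)$rank < 6) stop("gradient directions are not sufficiently non-collinear")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "gradient_table")
}

#' Evenly dispersed unit directions on the sphere
#'
#' Golden-section spiral scheme; used to emulate a multi-direction
#' acquisition (e.g. 60 directions at b = 1000 with 3 b = 0 volumes).
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# row-wise design matrix of the log-linear tensor model:
# ln S = ln S0 - b g' D g, parameters (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor_design <- function(gtab) {
  g <- gtab$bvecs
  b <- gtab$bvals
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit the diffusion tensor model
#'
#' Weighted log-linear least squares per voxel (weights = squared observed
#' signal, the standard WLS scheme for the log-transformed model). Voxels
#' with any non-positive signal are masked out (all-NA tensor row).
#'
#' @param dwi 4D array (X x Y x Z x N volumes) or V x N matrix of signals.
#' @param gtab A \code{gradient_table} with N entries.
#' @param voxel_mm Isotropic voxel size in mm (used downstream for
#'   world/voxel mapping).
#' @return A \code{tensor_field}: list with \code{D} (V x 6 matrix, order
#'   xx, yy, zz, xy, xz, yz), \code{S0}, \code{dims}, \code{voxel_mm}.
#' @export
fit_tensor <- function(dwi, gtab, voxel_mm = 1) {
  if (length(dim(dwi)) == 4) {
    dims <- dim(dwi)[1:3]
    S <- matrix(dwi, prod(dims), dim(dwi)[4])
  } else {
    dims <- c(nrow(dwi), 1L, 1L)
    S <- as.matrix(dwi)
  }
  if (ncol(S) != length(gtab$bvals))
    stop("signal volumes do not match the gradient table")
  X <- tensor_design(gtab)
  D <- matrix(NA_real_, nrow(S), 6)
  S0 <- rep(NA_real_, nrow(S))
  ok <- rowSums(S <= 0 | !is.finite(S)) == 0
  if (any(ok)) {
    Sok <- S[ok, , drop = FALSE]
    Y <- log(Sok)
    # per-voxel WLS; weights differ per voxel so solve voxel-wise
    fitted <- t(vapply(seq_len(nrow(Sok)), function(i) {
      w <- Sok[i, ]^2
      Xw <- X * w
      solve(crossprod(X, Xw), crossprod(Xw, Y[i, ]))[, 1]
    }, numeric(7)))
    S0[ok] <- exp(fitted[, 1])
    D[ok, ] <- fitted[, 2:7]
  }
  structure(list(D = D, S0 = S0, dims = dims, voxel_mm = voxel_mm),
            class = "tensor_field")
}

#' Predicted diffusion signal from a tensor (forward model)
#'
#' @param D Length-6 tensor (xx, yy, zz, xy, xz, yz) in mm^2/s.
#' @param gtab A \code{gradient_table}.
#' @param S0 Non-diffusion-weighted signal.
#' @return Signal vector, one entry per gradient-table row.
#' @export
tensor_signal <- function(D, gtab, S0 = 1) {
  g <- gtab$bvecs
  quad <- D[1] * g[, 1]^2 + D[2] * g[, 2]^2 + D[3] * g[, 3]^2 +
    2 * (D[4] * g[, 1] * g[, 2] + D[5] * g[, 1] * g[, 3] +
           D[6] * g[, 2] * g[, 3])
  S0 * exp(-gtab$bvals * quad)
}

#' Eigen-decomposition of a tensor field
#'
#' @param field A \code{tensor_field} (or V x 6 matrix).
#' @return List with \code{values} (V x 3, descending) and \code{e1}
#'   (V x 3 principal eigenvectors, unit length; NA rows propagate).
#' @export
tensor_eigen <- function(field) {
  D <- if (inherits(field, "tensor_field")) field$D else as.matrix(field)
  eig3_sym_cpp(D)
}

#' Fractional anisotropy from eigenvalues
#'
#' \code{FA = sqrt(3/2) * sqrt(sum((l - MD)^2)) / sqrt(sum(l^2))}; the zero
#' tensor is assigned FA 0.
#'
#' @param l1,l2,l3 Eigenvalues (vectors allowed).
#' @return FA values in [0, 1] for physical tensors.
#' @export
fa <- function(l1, l2, l3) {
  m <- (l1 + l2 + l3) / 3
  num <- (l1 - m)^2 + (l2 - m)^2 + (l3 - m)^2
  den <- l1^2 + l2^2 + l3^2
  out <- sqrt(1.5) * sqrt(num / den)
  out[den == 0] <- 0
  out
}

#' Mean diffusivity from eigenvalues
#'
#' @param l1,l2,l3 Eigenvalues (mm^2/s).
#' @return \code{(l1 + l2 + l3) / 3}.
#' @export
md <- function(l1, l2, l3) (l1 + l2 + l3) / 3

#' Scalar map container
#'
#' @param values 3D array of per-voxel values.
#' @param voxel_mm Isotropic voxel size (mm).
#' @return An object of class \code{scalar_map}.
#' @export
scalar_map <- function(values, voxel_mm = 1) {
  structure(list(values = values, voxel_mm = voxel_mm, dims = dim(values)),
            class = "scalar_map")
}

#' FA and MD maps of a tensor field
#'
#' @param field A \code{tensor_field}.
#' @return List of two \code{scalar_map}s, \code{fa} and \code{md}; NA
#'   tensors give NA voxels.
#' @export
tensor_scalar_maps <- function(field) {
  e <- tensor_eigen(field)
  fa_v <- fa(e$values[, 1], e$values[, 2], e$values[, 3])
  md_v <- md(e$values[, 1], e$values[, 2], e$values[, 3])
  list(fa = scalar_map(array(fa_v, field$dims), field$voxel_mm),
       md = scalar_map(array(md_v, field$dims), field$voxel_mm))
}

# shift a 3D logical array by one voxel along axis, padding with FALSE
shift_mask <- function(m, axis, by) {
  out <- array(FALSE, dim(m))
  n <- dim(m)[axis]
  src <- list(seq_len(dim(m)[1]), seq_len(dim(m)[2]), seq_len(dim(m)[3]))
  dst <- src
  if (by == 1) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
  else { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' White-matter skeleton mask from an FA map
#'
#' Thresholds the FA map (values at or above \code{threshold} are retained)
#' and applies 6-connected morphological erosion; voxels at the volume
#' border are eroded (out-of-volume neighbors count as background).
#'
#' @param fa_map A \code{scalar_map} of FA values.
#' @param threshold FA threshold in [0, 1] (default 0.7).
#' @param erosion_iters Number of erosion passes.
#' @return Logical 3D array.
#' @export
wm_skeleton <- function(fa_map, threshold = 0.7, erosion_iters = 1) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  m <- !is.na(fa_map$values) & fa_map$values >= threshold
  for (i in seq_len(erosion_iters)) {
    keep <- m
    for (axis in 1:3)
      for (by in c(-1, 1))
        keep <- keep & shift_mask(m, axis, by)
    m <- keep
  }
  m
}
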