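#' Population receptive field parameters
#'
#' A single isotropic 2D Gaussian receptive field in visual-field
#' coordinates: center \code{(x0, y0)} degrees from fixation, spread
#' \code{sigma} degrees, response amplitude \code{beta}, and model
#' goodness-of-fit \code{r} (Pearson correlation between prediction and
#' data). Polar angle and eccentricity are derived from the center.
#'
#' @param x0_deg,y0_deg Receptive-field center (degrees).
#' @param sigma_deg Gaussian spread (degrees, > 0).
#' @param beta Response amplitude (arbitrary units).
#' @param r Pearson correlation of the fitted model.
#' @return An object of class \code{prf_params}.
#' @export
prf_params <- function(x0_deg, y0_deg, sigma_deg, beta = NA_real_,
                       r = NA_real_) {
  if (sigma_deg <= 0) stop("sigma_deg must be positive")
  if (is.finite(r) && (r < -1 || r > 1)) stop("r must lie in [-1, 1]")
  structure(list(x0_deg = x0_deg, y0_deg = y0_deg, sigma_deg = sigma_deg,
                 beta = beta, r = r,
                 polar_angle_deg = atan2(y0_deg, x0_deg) * 180 / pi,
                 eccentricity_deg = sqrt(x0_deg^2 + y0_deg^2)),
            class = "prf_params")
}

#' @export
print.prf_params <- function(x, ...) {
  cat(sprintf(
    "pRF: center (%.2f, %.2f) deg, sigma %.2f deg, r = %.3f\n",
    x$x0_deg, x$y0_deg, x$sigma_deg, x$r))
  invisible(x)
}

#' Precomputed aperture design for pRF prediction
#'
#' Flattens an aperture sequence to a volumes-by-pixels matrix restricted to
#' pixels inside the stimulated field, with pixel coordinates and area
#' attached. Building this once and passing it to the fitting functions
#' avoids re-flattening the masks for every vertex.
#'
#' @param ap An \code{aperture_sequence}.
#' @return An object of class \code{aperture_design}.
#' @export
aperture_design <- function(ap) {
  if (inherits(ap, "aperture_design")) return(ap)
  g <- field_grid(ap$cfg)
  keep <- which(g$disk)
  d <- dim(ap$masks)
  A <- matrix(ap$masks, d[1], d[2] * d[3])[, keep, drop = FALSE]
  spacing <- 2 * ap$cfg$field_radius_deg / (ap$cfg$grid_n - 1)
  structure(list(A = A, px = g$xx[keep], py = g$yy[keep],
                 pixel_area = spacing^2, tr_s = ap$cfg$tr_s,
                 n_vol = d[1]),
            class = "aperture_design")
}

# stimulus drive of a Gaussian pRF: area-weighted aperture overlap per volume
prf_drive <- function(des, x0, y0, sigma) {
  g <- exp(-((des$px - x0)^2 + (des$py - y0)^2) / (2 * sigma^2))
  drop(des$A %*% g) * des$pixel_area
}

# causal convolution with the HRF kernel, truncated to the series length
convolve_hrf <- function(drive, kernel) {
  n <- length(drive)
  full <- stats::convolve(drive, rev(kernel), type = "open")
  full[seq_len(n)]
}

#' Predicted BOLD time series of a Gaussian pRF
#'
#' The per-volume stimulus drive (area-weighted overlap between the aperture
#' and the Gaussian receptive field) is convolved with the HRF kernel,
#' truncated to the aperture length, and z-scored. A pRF with essentially no
#' stimulus overlap yields a flat drive; the result is then all zeros and
#' carries attribute \code{degenerate = TRUE}.
#'
#' @param p A \code{prf_params}.
#' @param ap An \code{aperture_sequence} or prebuilt \code{aperture_design}.
#' @param h An \code{hrf_params}.
#' @return Numeric series of length T (z-scored), with attribute
#'   \code{"degenerate"}.
#' @export
predict_timeseries <- function(p, ap, h) {
  if (p$sigma_deg <= 0) stop("sigma must be positive")
  des <- aperture_design(ap)
  if (des$n_vol == 0) stop("empty aperture sequence")
  drive <- prf_drive(des, p$x0_deg, p$y0_deg, p$sigma_deg)
  k <- double_gamma_kernel(h, des$tr_s)
  y <- convolve_hrf(drive, k)
  s <- stats::sd(y)
  if (!is.finite(s) || s < 1e-12) {
    out <- rep(0, length(y))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (y - mean(y)) / s
  attr(out, "degenerate") <- FALSE
  out
}

#' Default pRF parameter lattice
#'
#' Polar grid of candidate centers (12 polar angles by 8 log-spaced
#' eccentricities up to the field radius) crossed with 6 log-spaced sigma
#' values.
#'
#' @param max_ecc_deg Largest candidate eccentricity (degrees).
#' @param n_angle,n_ecc,n_sigma Lattice resolution.
#' @param sigma_range Range of candidate sigmas (degrees).
#' @return Data frame with columns \code{x0}, \code{y0}, \code{sigma}.
#' @export
prf_lattice <- function(max_ecc_deg = 10.40, n_angle = 12, n_ecc = 8,
                        n_sigma = 6, sigma_range = c(0.2, 5)) {
  ang <- seq(0, 360, length.out = n_angle + 1)[-(n_angle + 1)] * pi / 180
  ecc <- exp(seq(log(max_ecc_deg / 20), log(max_ecc_deg),
                 length.out = n_ecc))
  sig <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                 length.out = n_sigma))
  centers <- expand.grid(ang = ang, ecc = ecc)
  grid <- expand.grid(idx = seq_len(nrow(centers)), sigma = sig)
  data.frame(x0 = centers$ecc[grid$idx] * cos(centers$ang[grid$idx]),
             y0 = centers$ecc[grid$idx] * sin(centers$ang[grid$idx]),
             sigma = grid$sigma)
}

# T x K matrix of z-scored lattice predictions (columns with zero variance
# are left as zeros and can never win the correlation stage)
lattice_predictions <- function(des, h, lattice) {
  k <- double_gamma_kernel(h, des$tr_s)
  P <- matrix(0, des$n_vol, nrow(lattice))
  for (j in seq_len(nrow(lattice))) {
    y <- convolve_hrf(prf_drive(des, lattice$x0[j], lattice$y0[j],
                                lattice$sigma[j]), k)
    s <- stats::sd(y)
    if (is.finite(s) && s > 1e-12) P[, j] <- (y - mean(y)) / s
  }
  P
}

#' Grid stage of the pRF fit
#'
#' Evaluates every lattice candidate against the series by Pearson
#' correlation and returns the best one; ties break toward the lowest
#' lattice index.
#'
#' @param series Numeric BOLD series (typically spatially smoothed).
#' @param ap Aperture sequence or design.
#' @param h \code{hrf_params}.
#' @param lattice Candidate data frame from \code{\link{prf_lattice}}.
#' @param predictions Optional precomputed matrix from an earlier call
#'   (internal reuse across vertices).
#' @return A \code{prf_params} at the winning lattice point, with \code{r}
#'   set.
#' @export
grid_fit <- function(series, ap, h, lattice = prf_lattice(),
                     predictions = NULL) {
  if (nrow(lattice) == 0) stop("empty parameter lattice")
  if (stats::sd(series) == 0) stop("degenerate fit: zero-variance series")
  des <- aperture_design(ap)
  if (is.null(predictions)) predictions <- lattice_predictions(des, h, lattice)
  r <- suppressWarnings(stats::cor(series, predictions))
  r[!is.finite(r)] <- -Inf
  j <- which.max(r)  # which.max returns the first (lowest-index) maximum
  prf_params(lattice$x0[j], lattice$y0[j], lattice$sigma[j],
             r = max(r[j], -1))
}

#' Nelder-Mead refinement of a pRF fit
#'
#' Minimizes \code{1 - Pearson r} over \code{(x0, y0, log sigma)} starting
#' from the grid-stage winner, on the (unsmoothed) series. If the simplex
#' ends below the starting correlation the start point is returned with
#' \code{warning_flag = TRUE}.
#'
#' @param series Numeric BOLD series.
#' @param ap Aperture sequence or design.
#' @param h \code{hrf_params}.
#' @param init Starting \code{prf_params}.
#' @param maxit Maximum simplex iterations.
#' @return A \code{prf_params} with \code{r} and \code{beta} set and a
#'   logical \code{warning_flag}.
#' @export
refine_fit <- function(series, ap, h, init, maxit = 400) {
  des <- aperture_design(ap)
  k <- double_gamma_kernel(h, des$tr_s)
  sz <- (series - mean(series)) / stats::sd(series)
  obj <- function(par) {
    y <- convolve_hrf(prf_drive(des, par[1], par[2], exp(par[3])), k)
    s <- stats::sd(y)
    if (!is.finite(s) || s < 1e-12) return(2)
    1 - sum(sz * (y - mean(y))) / (s * (length(y) - 1))
  }
  par0 <- c(init$x0_deg, init$y0_deg, log(init$sigma_deg))
  r0 <- 1 - obj(par0)
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  r1 <- 1 - opt$value
  if (!is.finite(r1) || r1 < r0) {
    out <- init
    out$r <- r0
    out$warning_flag <- TRUE
    return(out)
  }
  out <- prf_params(opt$par[1], opt$par[2], exp(opt$par[3]), r = min(r1, 1))
  pred <- convolve_hrf(prf_drive(des, out$x0_deg, out$y0_deg,
                                 out$sigma_deg), k)
  out$beta <- unname(stats::lm.fit(cbind(1, pred), series)$coefficients[2])
  out$warning_flag <- opt$convergence != 0
  out
}

#' Gaussian smoothing of a per-vertex map across a cortical sheet
#'
#' Distance-weighted Gaussian kernel smoothing over the sheet's 2D vertex
#' coordinates, with the kernel width given as full width at half maximum
#' (sigma = fwhm / 2.355). \code{fwhm_mm = 0} is the identity.
#'
#' @param map Numeric vector (one value per vertex) or matrix with one row
#'   per vertex (e.g. vertices x time).
#' @param sheet A \code{sheet_geometry}.
#' @param fwhm_mm Kernel FWHM in mm (>= 0).
#' @return Smoothed map, same shape as the input.
#' @export
smooth_sheet <- function(map, sheet, fwhm_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(map)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d2 <- as.matrix(stats::dist(sheet$pos))^2
  W <- exp(-d2 / (2 * sigma^2))
  W <- W / rowSums(W)
  if (is.matrix(map)) unname(W %*% map) else unname(drop(W %*% map))
}

#' Two-stage pRF fit over a whole sheet
#'
#' Runs the grid stage on sheet-smoothed series and the Nelder-Mead
#' refinement on the raw series, vertex by vertex. Vertices whose grid-stage
#' correlation falls below \code{r_floor} are not refined and are flagged
#' \code{degenerate}.
#'
#' @param series_mat T x V matrix of BOLD series (columns = vertices).
#' @param ap Aperture sequence or design.
#' @param h \code{hrf_params}.
#' @param sheet \code{sheet_geometry} used for pre-grid smoothing.
#' @param lattice Candidate lattice.
#' @param smooth_fwhm_mm FWHM of the grid-stage smoothing (mm); 0 disables.
#' @param refine Logical; run the refinement stage.
#' @param r_floor Grid-stage correlation below which a vertex is flagged
#'   degenerate and left at its grid parameters.
#' @return Data frame with one row per vertex: \code{x0, y0, sigma, beta,
#'   r_grid, r, polar_angle_deg, eccentricity_deg, degenerate}.
#' @export
fit_prf_sheet <- function(series_mat, ap, h, sheet = NULL,
                          lattice = prf_lattice(), smooth_fwhm_mm = 8.3,
                          refine = TRUE, r_floor = 0.1) {
  des <- aperture_design(ap)
  V <- ncol(series_mat)
  sm <- if (!is.null(sheet) && smooth_fwhm_mm > 0)
    t(smooth_sheet(t(series_mat), sheet, smooth_fwhm_mm)) else series_mat
  P <- lattice_predictions(des, h, lattice)
  Rg <- suppressWarnings(stats::cor(sm, P))
  Rg[!is.finite(Rg)] <- -Inf
  win <- apply(Rg, 1, which.max)
  r_grid <- Rg[cbind(seq_len(V), win)]
  out <- data.frame(x0 = lattice$x0[win], y0 = lattice$y0[win],
                    sigma = lattice$sigma[win], beta = NA_real_,
                    r_grid = r_grid, r = r_grid,
                    degenerate = !is.finite(r_grid) | r_grid < r_floor)
  if (refine) {
    for (v in seq_len(V)) {
      if (out$degenerate[v]) next
      init <- prf_params(out$x0[v], out$y0[v], out$sigma[v],
                         r = max(out$r_grid[v], -1))
      ref <- refine_fit(series_mat[, v], des, h, init)
      out$x0[v] <- ref$x0_deg
      out$y0[v] <- ref$y0_deg
      out$sigma[v] <- ref$sigma_deg
      out$beta[v] <- if (is.null(ref$beta)) NA_real_ else ref$beta
      out$r[v] <- ref$r
    }
  }
  out$polar_angle_deg <- atan2(out$y0, out$x0) * 180 / pi
  out$eccentricity_deg <- sqrt(out$x0^2 + out$y0^2)
  out
}
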