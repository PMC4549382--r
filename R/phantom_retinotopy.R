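#' Configuration of the retinotopic sheet phantom
#'
#' A flat cortical sheet carrying the mirror-symmetric retinotopic layout of
#' early visual cortex: polar angle progresses across each area band and
#' reverses at the V1/V2 and V2/V3 boundaries, eccentricity runs along the
#' orthogonal axis, and pRF size grows linearly with eccentricity. Bands are
#' ordered (outer ventral edge to outer dorsal edge) V3v, V2v, V1, V2d,
#' V3d, V3A.
#'
#' @param band_widths_mm Named widths of the V1 band (dorsal + ventral
#'   combined), the V2 and V3 bands (each half), and V3A, in mm.
#' @param spacing_mm Vertex spacing (mm).
#' @param n_ecc Number of vertices along the eccentricity axis.
#' @param ecc_range_deg Eccentricity at the first and last column (degrees).
#' @param sigma0_deg,sigma_slope pRF size at fixation (degrees) and its
#'   linear growth per degree of eccentricity.
#' @param noise_sd BOLD noise standard deviation as a fraction of the
#'   (unit) signal standard deviation.
#' @param seed Random seed for BOLD simulation.
#' @return An object of class \code{retinotopic_phantom_config}.
#' @export
retinotopic_phantom_config <- function(band_widths_mm = c(V1 = 12, V2 = 6,
                                                          V3 = 5, V3A = 5),
                                       spacing_mm = 1, n_ecc = 12,
                                       ecc_range_deg = c(0.5, 10),
                                       sigma0_deg = 0.5, sigma_slope = 0.25,
                                       noise_sd = 0.5, seed = 1L) {
  stopifnot(all(band_widths_mm > 0), spacing_mm > 0, n_ecc >= 1,
            ecc_range_deg[1] > 0, ecc_range_deg[2] > ecc_range_deg[1],
            sigma0_deg > 0, noise_sd >= 0)
  structure(list(band_widths_mm = band_widths_mm, spacing_mm = spacing_mm,
                 n_ecc = as.integer(n_ecc), ecc_range_deg = ecc_range_deg,
                 sigma0_deg = sigma0_deg, sigma_slope = sigma_slope,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "retinotopic_phantom_config")
}

#' Build the retinotopic sheet phantom
#'
#' Polar angle follows the classical reversal sequence across bands (upper
#' vertical meridian at the V1/V2 ventral border, horizontal meridian at
#' the V2/V3 borders, lower vertical meridian at the V1/V2 dorsal border);
#' each reversal row terminates its band. V3A is laid out as a full
#' hemifield band beyond dorsal V3. All pRF centers lie in the right
#' hemifield (x0 >= 0).
#'
#' @param cfg A \code{retinotopic_phantom_config}.
#' @return List with \code{sheet} (a \code{sheet_geometry}), \code{truth}
#'   (per-vertex data frame: x0, y0, sigma, polar_angle_deg,
#'   eccentricity_deg) and \code{labels} (ground-truth factor of
#'   \code{\link{visual_area_levels}}).
#' @export
make_retinotopic_phantom <- function(cfg = retinotopic_phantom_config()) {
  w <- cfg$band_widths_mm
  rows_of <- function(mm) max(2L, round(mm / cfg$spacing_mm))
  n_band_rows <- c(V3v = rows_of(w["V3"]), V2v = rows_of(w["V2"]),
                   V1 = rows_of(w["V1"]), V2d = rows_of(w["V2"]),
                   V3d = rows_of(w["V3"]), V3A = rows_of(w["V3A"]))
  n_band <- sum(n_band_rows)
  edges <- cumsum(n_band_rows)
  # continuous piecewise-linear polar-angle path over rows; knots at the
  # sheet edges and the five reversals, each reversal row ending its band
  knot_rows <- c(1L, edges)
  knot_phi <- c(90, 0, 90, -90, 0, -90, 90)
  phi <- stats::approx(knot_rows, knot_phi, xout = seq_len(n_band))$y
  band_name <- rep(names(n_band_rows), times = n_band_rows)
  labels_row <- band_name
  v1_rows <- band_name == "V1"
  labels_row[v1_rows] <- ifelse(phi[v1_rows] >= 0, "V1v", "V1d")

  sheet <- sheet_geometry(n_band, cfg$n_ecc, cfg$spacing_mm)
  ecc_col <- seq(cfg$ecc_range_deg[1], cfg$ecc_range_deg[2],
                 length.out = cfg$n_ecc)
  phi_v <- rep(phi, times = cfg$n_ecc)
  ecc_v <- rep(ecc_col, each = n_band)
  truth <- data.frame(
    x0 = ecc_v * cos(phi_v * pi / 180),
    y0 = ecc_v * sin(phi_v * pi / 180),
    sigma = cfg$sigma0_deg + cfg$sigma_slope * ecc_v,
    polar_angle_deg = phi_v,
    eccentricity_deg = ecc_v)
  labels <- factor(rep(labels_row, times = cfg$n_ecc),
                   levels = visual_area_levels())
  list(sheet = sheet, truth = truth, labels = labels, cfg = cfg)
}

#' Simulate BOLD series for every phantom vertex
#'
#' Forward-models each vertex's ground-truth pRF through the aperture
#' sequence and HRF (z-scored prediction) and adds independent Gaussian
#' noise with sd \code{noise_sd} (the prediction has unit sd, so
#' \code{noise_sd} is the noise-to-signal ratio).
#'
#' @param phantom Output of \code{\link{make_retinotopic_phantom}}.
#' @param ap Aperture sequence or design.
#' @param h \code{hrf_params}.
#' @param noise_sd Noise sd; defaults to the phantom configuration value.
#' @param seed Random seed; defaults to the phantom configuration value.
#' @return T x V matrix of BOLD series (columns = vertices).
#' @export
simulate_bold <- function(phantom, ap, h, noise_sd = phantom$cfg$noise_sd,
                          seed = phantom$cfg$seed) {
  stopifnot(noise_sd >= 0)
  des <- aperture_design(ap)
  k <- double_gamma_kernel(h, des$tr_s)
  tr <- phantom$truth
  G <- exp(-(outer(des$px, tr$x0, "-")^2 + outer(des$py, tr$y0, "-")^2) /
             matrix(2 * tr$sigma^2, length(des$px), nrow(tr), byrow = TRUE))
  drive <- (des$A %*% G) * des$pixel_area
  out <- apply(drive, 2, function(dr) {
    y <- convolve_hrf(dr, k)
    s <- stats::sd(y)
    if (!is.finite(s) || s < 1e-12) rep(0, length(y)) else (y - mean(y)) / s
  })
  set.seed(seed)
  out + matrix(stats::rnorm(length(out), sd = noise_sd),
               nrow(out), ncol(out))
}
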