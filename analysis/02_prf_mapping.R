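#!/usr/bin/env Rscript
# Simulates BOLD responses on the retinotopic sheet phantom, estimates the
# subject HRF from the photic-burst condition, and fits the two-stage pRF
# model (grid search on smoothed series, Nelder-Mead refinement on raw
# series). Writes the per-vertex parameter maps and a recovery summary
# against the phantom's ground truth.

suppressPackageStartupMessages(library(orseg))
dir.create("results", showWarnings = FALSE)
seed <- 20260926

phantom <- make_retinotopic_phantom(retinotopic_phantom_config(
  band_widths_mm = c(V1 = 8, V2 = 4, V3 = 3, V3A = 3), n_ecc = 8,
  noise_sd = 0.5, seed = seed))
scfg <- stimulus_config(grid_n = 61L)
run <- make_mapping_run(scfg)
des <- aperture_design(run$apertures)

# subject-level HRF from the burst condition: simulate the average response
# of a responsive vertex, then fit the double-gamma
h_true <- hrf_params(peak_delay_s = 5.8, undershoot_delay_s = 15,
                     peak_undershoot_ratio = 5.5)
sched <- make_burst_schedule(10, 1, 14)
k <- double_gamma_kernel(h_true, scfg$tr_s, 14 * scfg$tr_s)
set.seed(seed)
burst_series <- rep(0, 150)
for (o in seq(1, 150, by = 15))
  burst_series[o:(o + 14)] <- burst_series[o:(o + 14)] + 2 * k
burst_series <- burst_series + rnorm(150, sd = 0.3)
h_est <- fit_hrf(burst_series, sched, scfg$tr_s)
cat("HRF peak delay estimated at", round(h_est$peak_delay_s, 2),
    "s (generated with", h_true$peak_delay_s, "s), r2 =",
    round(h_est$r2, 3), "\n")

Y <- simulate_bold(phantom, des, h_est, noise_sd = 0.5, seed = seed)
fit <- fit_prf_sheet(Y, des, h_est, sheet = phantom$sheet,
                     smooth_fwhm_mm = 8.3)
fit$truth_x0 <- phantom$truth$x0
fit$truth_y0 <- phantom$truth$y0
fit$truth_sigma <- phantom$truth$sigma
fit$truth_label <- as.character(phantom$labels)
write.csv(fit, "results/prf_fits.csv", row.names = FALSE)

sig_err <- abs(fit$sigma - phantom$truth$sigma) / phantom$truth$sigma
ecc_err <- abs(fit$eccentricity_deg - phantom$truth$eccentricity_deg)
ang_err <- abs((fit$polar_angle_deg - phantom$truth$polar_angle_deg + 180)
               %% 360 - 180)
rec <- data.frame(metric = c("median_sigma_error_pct",
                             "median_ecc_error_deg",
                             "median_angle_error_deg",
                             "median_model_r", "degenerate_vertices"),
                  value = c(100 * median(sig_err), median(ecc_err),
                            median(ang_err), median(fit$r),
                            sum(fit$degenerate)))
write.csv(rec, "results/prf_recovery.csv", row.names = FALSE)
cat("pRF recovery at noise sd 0.5:",
    round(100 * median(sig_err), 1), "% median sigma error,",
    round(median(ecc_err), 3), "deg median eccentricity error,",
    round(median(ang_err), 2), "deg median polar-angle error over",
    nrow(fit), "vertices.\n")
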