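test_that("retinotopic phantom lays out mirror-reversed polar angle", {
  ph <- make_retinotopic_phantom()
  pm <- matrix(ph$truth$polar_angle_deg, ph$sheet$n_band, ph$sheet$n_ecc)
  lab <- matrix(as.character(ph$labels), ph$sheet$n_band, ph$sheet$n_ecc)

  # V1 spans the hemifield from upper to lower vertical meridian
  v1 <- pm[lab[, 1] %in% c("V1d", "V1v"), 1]
  expect_lt(min(v1), -89)
  expect_gt(max(v1), 60)
  expect_true(all(diff(v1) < 0) || all(diff(v1) > 0))

  # band boundaries are local extrema of the polar-angle profile, at the
  # meridian representations
  profile <- rowMeans(pm)
  ext <- orseg:::profile_extrema(profile, 30)
  expect_equal(length(ext), 5)
  expect_equal(profile[ext], c(0, 90, -90, 0, -90), tolerance = 1e-6)

  # sigma grows linearly with eccentricity
  fit <- lm(sigma ~ eccentricity_deg, data = ph$truth)
  expect_equal(unname(coef(fit)[2]), ph$cfg$sigma_slope, tolerance = 1e-9)

  # generators are reproducible
  expect_identical(make_retinotopic_phantom(), ph)
})

test_that("simulated BOLD is seeded, noise-scaled and faithful at zero noise", {
  ph <- make_retinotopic_phantom(
    retinotopic_phantom_config(band_widths_mm = c(V1 = 4, V2 = 2, V3 = 2,
                                                  V3A = 2), n_ecc = 3))
  cfg <- small_cfg(grid_n = 41L)
  run <- make_mapping_run(cfg)
  h <- hrf_params()
  y0 <- simulate_bold(ph, run$apertures, h, noise_sd = 0, seed = 1)
  des <- aperture_design(run$apertures)
  v <- 7
  pred <- predict_timeseries(prf_params(ph$truth$x0[v], ph$truth$y0[v],
                                        ph$truth$sigma[v]), des, h)
  expect_gt(cor(y0[, v], pred), 1 - 1e-9)

  y1 <- simulate_bold(ph, run$apertures, h, noise_sd = 0.5, seed = 2)
  y2 <- simulate_bold(ph, run$apertures, h, noise_sd = 0.5, seed = 2)
  expect_identical(y1, y2)
  expect_gt(sd(y1 - y0), 0.4)
  expect_lt(sd(y1 - y0), 0.6)
})

test_that("OR phantom construction matches its specification", {
  ph <- make_or_phantom()
  cfg <- ph$cfg

  # FA on non-blended centerline voxels equals the configured bundle FA
  fa_b <- fa(cfg$bundle_evals[1], cfg$bundle_evals[2], cfg$bundle_evals[3])
  for (b in seq_along(ph$centerlines)) {
    pts <- ph$centerlines[[b]]$points[seq(10, 290, by = 40), ]
    vox <- cbind(floor(pts[, 1]), floor(pts[, 2]), floor(pts[, 3])) + 1L
    on_line <- ph$fa$values[vox]
    blended_here <- ph$blended[vox]
    expect_true(all(abs(on_line[!blended_here] - fa_b) < 1e-6))
  }

  # background FA sits below the tracking threshold, CSF is isotropic
  bg <- ph$bundle_id == 0L & !ph$csf_mask
  expect_lt(max(ph$fa$values[bg]), 0.1)
  expect_lt(max(ph$fa$values[ph$csf_mask]), 1e-6)
  expect_equal(ph$md$values[which(ph$csf_mask)[1]], 3e-3, tolerance = 1e-9)

  # seed region touches every bundle; V3A target receives none
  expect_setequal(unique(ph$bundle_id[ph$seed_mask]), 1:6)
  v3a <- ph$label_vol == match("V3A", visual_area_levels())
  expect_true(all(ph$bundle_id[v3a] == 0L))

  # targets aligned with bundle terminations: every bundle end voxel labeled
  for (b in seq_along(ph$centerlines)) {
    endv <- floor(ph$centerlines[[b]]$points[300, ]) + 1L
    expect_equal(visual_area_levels()[ph$label_vol[endv[1], endv[2], endv[3]]],
                 ph$bundle_labels[b])
  }

  # overlapping geometry is refused
  expect_error(make_or_phantom(or_phantom_config(bundle_radius_mm = 2.5)),
               "overlapping")

  expect_identical(make_or_phantom(), ph)
})

test_that("labeled tractogram plants violations exactly as configured", {
  ph <- make_or_phantom()
  lt <- make_labeled_tractogram(
    labeled_tractogram_config(n_violations = c(a = 10, b = 2, c = 2, d = 2),
                              seed = 8), ph)
  expect_equal(sum(lt$truth$code == "a"), 10)
  # every rule-a violator crosses the midsagittal plane
  a_idx <- which(lt$truth$code == "a")
  crosses <- vapply(lt$tractogram$streamlines[a_idx],
                    function(m) min(m[, 1]) < 0, logical(1))
  expect_true(all(crosses))

  # streamline spacing honors the step size
  sp <- sqrt(rowSums(diff(lt$tractogram$streamlines[[1]])^2))
  expect_true(all(sp <= 0.2 + 1e-6))

  expect_identical(
    make_labeled_tractogram(labeled_tractogram_config(seed = 9), ph),
    make_labeled_tractogram(labeled_tractogram_config(seed = 9), ph))
})
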