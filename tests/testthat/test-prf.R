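test_that("pRF predictions behave at the edges of the model", {
  fx <- mapping_fixture()
  # a pRF far outside the stimulated field never sees the stimulus
  far <- predict_timeseries(prf_params(100, 100, 1), fx$design, fx$hrf)
  expect_true(attr(far, "degenerate"))
  expect_true(all(far == 0))

  # full-field coverage at every volume gives a constant drive
  cfg <- small_cfg(grid_n = 41L)
  masks <- array(1L, c(30, 41, 41))
  g <- orseg:::field_grid(cfg)
  for (k in 1:30) masks[k, , ] <- as.integer(g$disk)
  ap_full <- orseg:::new_aperture_sequence(masks, (0:29) * cfg$tr_s, cfg)
  drv <- orseg:::prf_drive(aperture_design(ap_full), 1, 1, 2)
  expect_equal(diff(range(drv)), 0)

  # self-consistency: prediction correlates 1 with a series built from the
  # same parameters
  p <- prf_params(3, -2, 1.2)
  y1 <- predict_timeseries(p, fx$design, fx$hrf)
  y2 <- predict_timeseries(p, fx$design, fx$hrf)
  expect_gt(cor(y1, y2), 1 - 1e-9)

  expect_error(predict_timeseries(prf_params(0, 0, -1), fx$design, fx$hrf),
               "sigma")
})

test_that("predictions are stable under pixel-grid refinement", {
  # doubling the default raster changes predictions by < 1% RMS for
  # typical pRF sizes (quantization error grows as sigma shrinks toward
  # the pixel spacing)
  coarse <- make_mapping_run(stimulus_config(grid_n = 101L))$apertures
  fine <- make_mapping_run(stimulus_config(grid_n = 201L))$apertures
  h <- hrf_params()
  for (p in list(prf_params(3, 2, 1.5), prf_params(-5, 1, 2.5))) {
    yc <- predict_timeseries(p, coarse, h)
    yf <- predict_timeseries(p, fine, h)
    expect_lt(sqrt(mean((yc - yf)^2)) / sqrt(mean(yf^2)), 0.01)
  }
})

test_that("grid stage finds the generating lattice point", {
  fx <- mapping_fixture()
  lattice <- prf_lattice(n_angle = 8, n_ecc = 5, n_sigma = 4)
  j <- 47
  y <- predict_timeseries(prf_params(lattice$x0[j], lattice$y0[j],
                                     lattice$sigma[j]), fx$design, fx$hrf)
  fit <- grid_fit(y, fx$design, fx$hrf, lattice)
  expect_equal(c(fit$x0_deg, fit$y0_deg, fit$sigma_deg),
               c(lattice$x0[j], lattice$y0[j], lattice$sigma[j]))
  expect_gt(fit$r, 1 - 1e-9)

  # Pearson correlation is invariant to affine rescaling of the series
  fit2 <- grid_fit(3 * y + 7, fx$design, fx$hrf, lattice)
  expect_equal(fit2$x0_deg, fit$x0_deg)
  expect_equal(fit2$sigma_deg, fit$sigma_deg)

  expect_error(grid_fit(rep(0, length(y)), fx$design, fx$hrf, lattice),
               "zero-variance")
})

test_that("simplex refinement recovers noiseless parameters and never
           degrades the fit", {
  fx <- mapping_fixture()
  truth <- prf_params(4.2, -1.7, 1.1)
  y <- predict_timeseries(truth, fx$design, fx$hrf)

  # starting at the truth stays at the truth
  at_truth <- refine_fit(y, fx$design, fx$hrf, truth)
  expect_lt(abs(at_truth$x0_deg - truth$x0_deg), 1e-4)
  expect_lt(abs(at_truth$sigma_deg - truth$sigma_deg), 1e-4)

  # recovery from a displaced start inside the field
  init <- prf_params(2, 1, 2)
  rec <- refine_fit(y, fx$design, fx$hrf, init)
  expect_lt(abs(rec$x0_deg - truth$x0_deg), 0.1)
  expect_lt(abs(rec$y0_deg - truth$y0_deg), 0.1)
  expect_lt(abs(rec$sigma_deg - truth$sigma_deg) / truth$sigma_deg, 0.05)

  # refined r never falls below the grid-stage r on the same series
  set.seed(21)
  lattice <- prf_lattice(n_angle = 8, n_ecc = 5, n_sigma = 4)
  for (i in 1:5) {
    yn <- y + rnorm(length(y), sd = 0.5)
    g <- grid_fit(yn, fx$design, fx$hrf, lattice)
    r <- refine_fit(yn, fx$design, fx$hrf, g)
    expect_gte(r$r + 1e-12, cor(yn, predict_timeseries(g, fx$design, fx$hrf)))
  }
})

test_that("sheet smoothing matches the closed-form Gaussian kernel", {
  sh <- sheet_geometry(21, 21)
  x <- rnorm(21 * 21)
  expect_identical(smooth_sheet(x, sh, 0), x)
  expect_equal(smooth_sheet(rep(2.5, 21 * 21), sh, 6),
               rep(2.5, 21 * 21), tolerance = 1e-12)

  ctr <- orseg:::sheet_index(sh, 11, 11)
  imp <- rep(0, 21 * 21)
  imp[ctr] <- 1
  sm <- smooth_sheet(imp, sh, 5)
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  w <- exp(-as.matrix(dist(sh$pos))[, ctr]^2 / (2 * sigma^2))
  w <- w / sum(w)
  expect_lt(max(abs(sm - w)) / max(w), 0.02)

  expect_error(smooth_sheet(x, sh, -1), "non-negative")
})
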