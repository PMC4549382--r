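test_that("wedge apertures step, tile and stay inside the field", {
  cfg <- small_cfg(grid_n = 101L)
  w <- make_wedge_apertures(cfg, 2)
  expect_equal(dim(w$masks)[1], 2 * cfg$wedge_vols_per_rev)
  # periodicity: volume k and k + vols_per_rev are identical
  expect_identical(w$masks[1, , ], w$masks[22, , ])
  expect_identical(w$masks[5, , ], w$masks[26, , ])

  # every mask covers the analytic angular fraction of the disk, up to
  # pixel quantization at the wedge edges
  g <- orseg:::field_grid(cfg)
  frac <- vapply(1:21, function(k) sum(w$masks[k, , ]) / sum(g$disk),
                 numeric(1))
  expect_true(all(abs(frac - cfg$wedge_width_deg / 360) < 0.005))
  # support confined to the field disk
  flat <- matrix(w$masks, nrow = dim(w$masks)[1])
  expect_true(all(flat[, !as.vector(g$disk)] == 0))

  # 21 steps of width 360/21 tile the disk exactly once
  cfg_t <- stimulus_config(wedge_width_deg = 360 / 21, grid_n = 101L)
  wt <- make_wedge_apertures(cfg_t, 1)
  cover <- apply(wt$masks, c(2, 3), sum)
  expect_true(all(cover[g$disk] == 1))
  expect_true(all(cover[!g$disk] == 0))

  # clockwise and counter-clockwise are mirror schedules
  wc <- make_wedge_apertures(cfg, 1, "cw")
  wcc <- make_wedge_apertures(cfg, 1, "ccw")
  expect_identical(wc$masks[1, , ], wcc$masks[1, , ])
  expect_error(make_wedge_apertures(cfg, 0), "n_rev")
})

test_that("ring width schedule is log-spaced between the configured widths", {
  cfg <- small_cfg()
  rs <- ring_width_schedule(cfg)
  expect_equal(rs$width[1], 0.11)
  expect_equal(rs$width[nrow(rs)], 4.62)
  expect_true(all(diff(rs$width) > 0))
  expect_true(all(diff(log(rs$width)) - diff(log(rs$width))[1] < 1e-12))
  # ring sweeps fixation to field edge within a revolution
  expect_equal(rs$inner[1], 0, tolerance = 1e-12)
  expect_equal(rs$outer[nrow(rs)], cfg$field_radius_deg)
})

test_that("ring apertures expand, contract symmetrically and stay in-field", {
  cfg <- small_cfg()
  re <- make_ring_apertures(cfg, 1, "expand")
  rc <- make_ring_apertures(cfg, 1, "contract")
  n <- cfg$ring_vols_per_rev
  for (k in 1:n) expect_identical(re$masks[k, , ], rc$masks[n + 1 - k, , ])
  # periodicity over revolutions
  re2 <- make_ring_apertures(cfg, 2, "expand")
  expect_identical(re2$masks[3, , ], re2$masks[n + 3, , ])
  g <- orseg:::field_grid(cfg)
  flat <- matrix(re$masks, nrow = dim(re$masks)[1])
  expect_true(all(flat[, !as.vector(g$disk)] == 0))
})

test_that("burst schedules have the closed-form composition", {
  s <- make_burst_schedule(10, 1, 14)
  expect_length(s$labels, 150)
  expect_equal(sum(s$labels == "stimulus"), 10)

  expect_length(make_burst_schedule(0, 1, 14)$labels, 0)

  s3 <- make_burst_schedule(3, 2, 2)
  expect_length(s3$labels, 12)
  expect_equal(which(s3$labels == "stimulus"), c(1, 2, 5, 6, 9, 10))

  # property: total length equals n_runs * (stim + rest) across a sweep
  for (nr in c(1, 4)) for (sv in c(0, 2)) for (rv in c(1, 3)) {
    expect_length(make_burst_schedule(nr, sv, rv)$labels, nr * (sv + rv))
  }
})

test_that("mapping run combines wedge and ring with appended blanks", {
  cfg <- small_cfg()
  run <- make_mapping_run(cfg)
  expect_equal(dim(run$apertures$masks)[1], 234)  # 10*21 = 14*15, + 24 blank
  expect_equal(sum(run$schedule$labels == "blank"), 24)

  wedge <- make_wedge_apertures(cfg, 10)
  for (k in c(1, 57, 210))
    expect_true(all(run$apertures$masks[k, , ] >= wedge$masks[k, , ]))
  for (k in 211:234) expect_true(all(run$apertures$masks[k, , ] == 0))

  expect_error(make_mapping_run(cfg, wedge_revs = 9), "lengths differ")
})
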