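test_that("visitation maps count each streamline once per voxel", {
  # straight streamline along a voxel row of 10 voxels
  line <- cbind(seq(0.1, 9.9, by = 0.2), 0.5, 0.5)
  vm <- visitation_map(list(line), dims = c(10, 3, 3), voxel_mm = 1)
  expect_equal(sum(vm$support), 10)
  expect_true(all(vm$counts[vm$support] == 1))

  # duplicating a streamline doubles counts, not support
  vm2 <- visitation_map(list(line, line), dims = c(10, 3, 3), voxel_mm = 1)
  expect_equal(vm2$support, vm$support)
  expect_equal(vm2$counts[vm2$support], rep(2L, 10))

  # empty segment, empty support
  vm0 <- visitation_map(list(), dims = c(10, 3, 3), voxel_mm = 1)
  expect_false(any(vm0$support))

  # densifying the points leaves the support unchanged
  dense <- cbind(seq(0.1, 9.9, by = 0.05), 0.5, 0.5)
  vmd <- visitation_map(list(dense), dims = c(10, 3, 3), voxel_mm = 1)
  expect_equal(vmd$support, vm$support)
})

test_that("segment scalar means average over the support", {
  line <- cbind(seq(0.1, 1.9, by = 0.2), 0.5, 0.5)
  vm <- visitation_map(list(line), dims = c(2, 1, 1), voxel_mm = 1)
  fa_m <- scalar_map(array(c(0.2, 0.8), c(2, 1, 1)))
  md_m <- scalar_map(array(c(1e-3, 3e-3), c(2, 1, 1)))
  out <- segment_mean_scalars(vm, fa_m, md_m)
  expect_equal(unname(out["fa"]), 0.5)
  expect_equal(unname(out["md"]), 2e-3)

  vm0 <- visitation_map(list(), dims = c(2, 1, 1), voxel_mm = 1)
  expect_error(segment_mean_scalars(vm0, fa_m, md_m), "empty")
})

test_that("paired t matches the closed form and is antisymmetric", {
  a <- c(5, 7, 9)
  b <- a - c(1, 2, 3)
  res <- paired_t(a, b)
  d <- a - b
  t_direct <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_direct)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-abs(t_direct), 2))

  rev <- paired_t(b, a)
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p, res$p)

  set.seed(6)
  x <- rnorm(8)
  expect_error(paired_t(x, x), "zero-variance")
  expect_equal(paired_t(x, x + rnorm(8))$df, 7)
})

test_that("Bonferroni correction caps scaled probabilities at one", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_equal(bonferroni(c(0.2, 0.7)), c(0.4, 1))
  expect_equal(bonferroni(0.3, 1), 0.3)
})

test_that("repeated-measures ANOVA reproduces a brute-force SS partition", {
  # hand-worked 3-subject 2x2 within-subject table
  d <- expand.grid(subject = factor(1:3), segment = c("s1", "s2"),
                   hemisphere = c("L", "R"))
  d$y <- c(10, 12, 11, 14, 15, 16, 9, 11, 12, 13, 16, 15)
  res <- rm_anova(d, "y")
  ss <- attr(res, "ss")

  # independent partition by direct marginal means
  gm <- mean(d$y)
  ss_subj <- 4 * sum((tapply(d$y, d$subject, mean) - gm)^2)
  ss_a <- 6 * sum((tapply(d$y, d$segment, mean) - gm)^2)
  ss_b <- 6 * sum((tapply(d$y, d$hemisphere, mean) - gm)^2)
  cell <- tapply(d$y, list(d$segment, d$hemisphere), mean)
  ss_ab <- 3 * sum((cell - outer(rowMeans(cell) - gm, colMeans(cell) - gm,
                                 "+") - gm)^2)
  ss_tot <- sum((d$y - gm)^2)
  expect_equal(ss$subject, ss_subj, tolerance = 1e-9)
  expect_equal(ss$segment, ss_a, tolerance = 1e-9)
  expect_equal(ss$hemisphere, ss_b, tolerance = 1e-9)
  expect_equal(ss[["segment:hemisphere"]], ss_ab, tolerance = 1e-9)
  expect_equal(ss$total,
               ss$subject + ss$segment + ss$hemisphere +
                 ss[["segment:hemisphere"]] + ss$error,
               tolerance = 1e-9)
  expect_equal(ss$total, ss_tot, tolerance = 1e-9)

  # degrees of freedom follow the within-subject strata
  expect_equal(res$df_effect, c(1, 1, 1))
  expect_equal(res$df_error, c(2, 2, 2))

  # a constant response has all F = 0
  d0 <- d
  d0$y <- 5
  res0 <- rm_anova(d0, "y")
  expect_equal(res0$F, c(0, 0, 0))

  # incomplete designs are refused
  expect_error(rm_anova(d[-1, ], "y"), "incomplete")
})

test_that("ANOVA F statistics agree with aov strata on simulated data", {
  set.seed(12)
  d <- expand.grid(subject = factor(1:30), segment = c("dorsal", "ventral"),
                   hemisphere = c("L", "R"))
  d$y <- rnorm(120) + ifelse(d$segment == "ventral", 0.8, 0) +
    rep(rnorm(30), 4)
  res <- rm_anova(d, "y")
  expect_equal(res$df_error, c(29, 29, 29))
  expect_lt(res$p[res$effect == "segment"], 0.001)
  expect_gt(res$p[res$effect == "hemisphere"], 0.01)
})
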