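toy_anat <- function() {
  wall <- array(FALSE, c(30, 50, 30))
  wall[5:24, 21:40, 13] <- TRUE  # wall layer at z centers 12.5
  anatomy_model(lgn_mm = c(10, 10, 20), midsagittal_x = 0,
                temporal_plane_y = 4, ventricle_mask = wall,
                ventricle_normal = c(0, 0, 1), voxel_mm = 1,
                dims = c(30, 50, 30))
}

toy_tract <- function(paths) {
  sl <- lapply(paths, resample_polyline, step_mm = 0.2)
  orseg:::new_tractogram(sl, rep(NA_integer_, length(sl)),
                         rep(NA_integer_, length(sl)), tracking_params(),
                         voxel_mm = 1, dims = c(30, 50, 30))
}

test_that("each rejection heuristic fires on its constructed violation", {
  anat <- toy_anat()
  lgn <- anat$lgn_mm
  paths <- list(
    ok = rbind(lgn, c(12, 30, 18), c(14, 45, 16)),
    a = rbind(lgn, c(-1, 10, 20)),                  # crosses the midline
    b = rbind(lgn, c(10, 10, 33)),                  # rises vertically
    c = rbind(lgn, c(10, 2, 12)),                   # antero-inferior plunge
    d = rbind(c(15, 21, 13.2), c(15, 39, 13.2)))    # hugs the wall
  codes <- apply_rejection_rules(toy_tract(paths), anat)
  expect_equal(unname(codes), c("none", "a", "b", "c", "d"))

  # precedence: a streamline violating both a and b is coded a
  both <- toy_tract(list(rbind(lgn, c(-2, 10, 35))))
  expect_equal(apply_rejection_rules(both, anat), "a")
})

test_that("termination labeling collects areas near the cortical endpoint", {
  anat <- toy_anat()
  labs_vol <- array(0L, c(30, 50, 30))
  lv <- visual_area_levels()
  labs_vol[12, 45, 18] <- match("V2d", lv)
  labs_vol[14, 45, 18] <- match("V1d", lv)
  t <- toy_tract(list(rbind(anat$lgn_mm, c(11, 44.5, 17.5)),
                      rbind(anat$lgn_mm, c(13, 44.5, 17.5)),
                      rbind(anat$lgn_mm, c(25, 44.5, 28))))
  out <- label_terminations(t, labs_vol, anat, r_assign_mm = 2)
  expect_equal(out[[1]], "V2d")              # only V2d within reach
  expect_equal(out[[2]], c("V1d", "V2d"))    # equidistant between both
  expect_equal(out[[3]], character(0))       # far from any label
})

test_that("Boolean segmentation schemes implement the AND/NOT criteria", {
  sets <- list(c("V2d"), c("V1d", "V1v"), character(0), c("V1v"),
               c("V1d", "V2d"), c("V3d", "V3v"), c("V2v", "V3v"))
  vf <- segment_visual_field(sets)
  expect_equal(as.character(vf),
               c("dorsal", "excluded", "excluded", "ventral", "dorsal",
                 "excluded", "ventral"))
  hier <- segment_hierarchy(sets)
  expect_equal(as.character(hier),
               c("V2", "V1", "excluded", "V1", "excluded", "V3", "excluded"))

  # the two schemes yield exactly five segment labels overall
  expect_setequal(c(setdiff(levels(vf), "excluded"),
                    setdiff(levels(hier), "excluded")),
                  c("dorsal", "ventral", "V1", "V2", "V3"))
})

test_that("segment counting, normalization and the control ratio are exact", {
  a <- factor(rep(c("dorsal", "ventral"), c(60, 40)),
              levels = c("dorsal", "ventral", "excluded"))
  tab <- count_segments(a, "L")
  expect_equal(tab$count, c(60, 40))
  expect_equal(tab$percent, c(60, 40))
  expect_equal(sum(tab$percent), 100)

  all_ex <- factor(rep("excluded", 5),
                   levels = c("dorsal", "ventral", "excluded"))
  expect_error(count_segments(all_ex), "undefined percentage")

  # counts are invariant to streamline order
  expect_equal(count_segments(sample(a), "L")$count, tab$count)

  expect_equal(unname(normalize_by_area(c(V1 = 100), c(V1 = 50))), 2)
  counts <- c(V1 = 100, V2 = 60, V3 = 30)
  areas <- c(V1 = 200, V2 = 40, V3 = 30)
  norm <- normalize_by_area(counts, areas)
  expect_equal(unname(norm), c(0.5, 1.5, 1))
  # halving under doubled areas (scale equivariance)
  expect_equal(unname(normalize_by_area(counts, 2 * areas)), c(0.25, 0.75, 0.5))
  # area normalization can invert the raw-count ordering
  expect_equal(names(which.max(counts)), "V1")
  expect_equal(names(which.max(norm)), "V2")
  expect_error(normalize_by_area(c(V1 = 1), c(V1 = 0)), "positive")

  expect_equal(false_positive_rate(c(V1 = 50, V2 = 30, V3 = 15, V3A = 0))$ratio, 0)
  expect_equal(false_positive_rate(c(V1 = 40, V2 = 30, V3 = 25, V3A = 5))$ratio,
               5 / 95)
  expect_error(false_positive_rate(c(V1 = 0, V2 = 0, V3 = 0, V3A = 1)),
               "positive")
})

test_that("the labeled synthetic tractogram is classified without error", {
  ph <- make_or_phantom()
  lt <- make_labeled_tractogram(labeled_tractogram_config(seed = 3), ph)
  codes <- apply_rejection_rules(lt$tractogram, lt$anat)
  expect_equal(codes, lt$truth$code)

  labs <- label_terminations(lt$tractogram, ph$label_vol, lt$anat)
  acc <- lt$truth$code == "none"
  got <- vapply(labs[acc], paste, character(1), collapse = "+")
  expect_equal(got, lt$truth$label[acc])

  # rejection + segmentation partitions every streamline exactly once
  vf <- segment_visual_field(labs)
  state <- ifelse(codes != "none", "rejected", as.character(vf))
  expect_true(all(state %in% c("rejected", "dorsal", "ventral", "excluded")))
  expect_equal(sum(state == "rejected"), sum(lt$truth$code != "none"))

  # zero violations, zero jitter: everything accepted
  clean <- make_labeled_tractogram(
    labeled_tractogram_config(n_violations = c(a = 0, b = 0, c = 0, d = 0),
                              jitter_mm = 0, seed = 4), ph)
  expect_true(all(apply_rejection_rules(clean$tractogram, clean$anat) ==
                    "none"))
})
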