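#' Anatomical reference model for streamline rejection
#'
#' Geometric referents of the four rejection heuristics: the midsagittal
#' plane, the LGN centroid, a coronal plane at the temporal pole, and the
#' medial-wall mask of the posterior horn of the lateral ventricle with its
#' plane normal. The anterior direction is decreasing y and superior is +z;
#' the hemisphere under analysis lies on the side of the midsagittal plane
#' containing the LGN.
#'
#' @param lgn_mm LGN centroid (world mm).
#' @param midsagittal_x x-coordinate of the midsagittal plane (mm).
#' @param temporal_plane_y y-coordinate of the temporal-pole coronal plane
#'   (mm); points with smaller y are anterior to it.
#' @param ventricle_mask Logical 3D array marking the ventricle medial wall.
#' @param ventricle_normal Unit normal of the wall plane.
#' @param voxel_mm,dims Grid geometry the masks live on.
#' @return An object of class \code{anatomy_model}.
#' @export
anatomy_model <- function(lgn_mm, midsagittal_x = 0, temporal_plane_y,
                          ventricle_mask = NULL,
                          ventricle_normal = c(1, 0, 0),
                          voxel_mm = 1, dims = NULL) {
  ventricle_normal <- ventricle_normal / sqrt(sum(ventricle_normal^2))
  structure(list(lgn_mm = lgn_mm, midsagittal_x = midsagittal_x,
                 temporal_plane_y = temporal_plane_y,
                 ventricle_mask = ventricle_mask,
                 ventricle_normal = ventricle_normal,
                 side = sign(lgn_mm[1] - midsagittal_x),
                 voxel_mm = voxel_mm,
                 dims = if (is.null(dims) && !is.null(ventricle_mask))
                   dim(ventricle_mask) else dims),
            class = "anatomy_model")
}

# 26-connected dilation by one voxel (Chebyshev ball of radius 1)
dilate_mask <- function(m) {
  for (axis in 1:3) {
    grown <- m
    for (by in c(-1, 1)) grown <- grown | shift_mask(m, axis, by)
    m <- grown
  }
  m
}

#' Apply the four anatomical rejection heuristics
#'
#' Streamlines are rejected if they (a) cross to the contralateral
#' hemisphere, (b) project superiorly from the LGN (initial 5 mm mean
#' direction elevated more than 45 degrees), (c) project antero-inferiorly
#' into the temporal pole (any point both anterior to the temporal-pole
#' plane and inferior to the LGN), or (d) run parallel to the medial wall of
#' the ventricle's posterior horn (at least half of the points within one
#' voxel of the wall mask with local tangent within 20 degrees of the wall
#' plane). The first matching rule in the order a, b, c, d is reported.
#'
#' @param t A \code{tractogram}.
#' @param anat An \code{anatomy_model} in the same world frame.
#' @param initial_mm Length of the initial segment for rule (b).
#' @param elevation_deg Elevation threshold for rule (b), degrees.
#' @param wall_fraction Minimum fraction of points near the wall, rule (d).
#' @param parallel_deg Maximum tangent-to-wall-plane angle, rule (d).
#' @return Character vector of per-streamline codes
#'   (\code{"none","a","b","c","d"}).
#' @export
apply_rejection_rules <- function(t, anat, initial_mm = 5,
                                  elevation_deg = 45, wall_fraction = 0.5,
                                  parallel_deg = 20) {
  wall <- if (!is.null(anat$ventricle_mask)) dilate_mask(anat$ventricle_mask)
  sin_par <- sin(parallel_deg * pi / 180)
  vapply(t$streamlines, function(m) {
    if ((min(m[, 1]) - anat$midsagittal_x) * anat$side < 0 ||
        (max(m[, 1]) - anat$midsagittal_x) * anat$side < 0)
      return("a")
    # rule b: initial segment from the thalamic (LGN-proximal) end
    d_first <- sum((m[1, ] - anat$lgn_mm)^2)
    d_last <- sum((m[nrow(m), ] - anat$lgn_mm)^2)
    mm <- if (d_first <= d_last) m else m[rev(seq_len(nrow(m))), , drop = FALSE]
    step <- sqrt(sum((mm[min(2, nrow(mm)), ] - mm[1, ])^2))
    k <- min(nrow(mm), max(2, ceiling(initial_mm / max(step, 1e-9)) + 1))
    v <- mm[k, ] - mm[1, ]
    elev <- atan2(v[3], sqrt(v[1]^2 + v[2]^2)) * 180 / pi
    if (elev > elevation_deg) return("b")
    if (any(m[, 2] < anat$temporal_plane_y & m[, 3] < anat$lgn_mm[3]))
      return("c")
    if (!is.null(wall) && nrow(m) >= 3) {
      vox <- points_to_flat_voxels(m, anat$voxel_mm, anat$dims)
      near <- !is.na(vox) & wall[vox]
      tang <- m[c(2:nrow(m), nrow(m)), ] - m[c(1, 1:(nrow(m) - 1)), ]
      tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
      par_wall <- abs(tang %*% anat$ventricle_normal) < sin_par
      if (mean(near & drop(par_wall)) >= wall_fraction) return("d")
    }
    "none"
  }, character(1))
}

#' Label streamline terminations by visual area
#'
#' The cortical endpoint (the endpoint farther from the LGN) collects the
#' labels of all area voxels whose centers lie within \code{r_assign_mm} of
#' it; an empty set means the streamline terminates away from any labeled
#' cortex and is excluded downstream.
#'
#' @param t A \code{tractogram}.
#' @param label_vol Integer 3D array; 0 = unlabeled, values index
#'   \code{\link{visual_area_levels}} (1 = V1d ... 7 = V3A).
#' @param anat An \code{anatomy_model} (for the LGN position).
#' @param r_assign_mm Assignment radius around the endpoint (mm).
#' @return List of character vectors (possibly empty), one per streamline.
#' @export
label_terminations <- function(t, label_vol, anat, r_assign_mm = 2) {
  stopifnot(all(dim(label_vol) == t$dims))
  lab_idx <- which(label_vol > 0)
  lab_ijk <- arrayInd(lab_idx, dim(label_vol))
  lab_centers <- (lab_ijk - 0.5) * t$voxel_mm
  lab_codes <- label_vol[lab_idx]
  lv <- visual_area_levels()
  ep <- streamline_endpoints(t)
  lapply(seq_len(nrow(ep)), function(i) {
    p1 <- ep[i, 1:3]; p2 <- ep[i, 4:6]
    p <- if (sum((p1 - anat$lgn_mm)^2) >= sum((p2 - anat$lgn_mm)^2)) p1 else p2
    d2 <- (lab_centers[, 1] - p[1])^2 + (lab_centers[, 2] - p[2])^2 +
      (lab_centers[, 3] - p[3])^2
    sort(unique(lv[lab_codes[d2 <= r_assign_mm^2]]))
  })
}

#' Visual-field Boolean segmentation
#'
#' Streamlines terminating exclusively in dorsal areas (V1d, V2d, V3d,
#' lower visual field) form the dorsal segment; exclusively ventral
#' terminations (V1v, V2v, V3v, upper field) form the ventral segment;
#' streamlines common to both representations, unlabeled streamlines, and
#' control-region terminations are excluded.
#'
#' @param label_sets List of per-streamline termination label sets.
#' @return Factor with levels \code{dorsal, ventral, excluded}.
#' @export
segment_visual_field <- function(label_sets) {
  dorsal <- c("V1d", "V2d", "V3d")
  ventral <- c("V1v", "V2v", "V3v")
  out <- vapply(label_sets, function(s) {
    if (length(s) == 0) return("excluded")
    if (all(s %in% dorsal)) return("dorsal")
    if (all(s %in% ventral)) return("ventral")
    "excluded"
  }, character(1))
  factor(out, levels = c("dorsal", "ventral", "excluded"))
}

#' Hierarchy Boolean segmentation
#'
#' Streamlines projecting exclusively to one visual area (its dorsal and
#' ventral components combined) form that area's segment: V1 means
#' terminations within \{V1d, V1v\} but not V2 or V3 maps, and likewise for
#' V2 and V3. Mixed-area and unlabeled terminations are excluded.
#'
#' @param label_sets List of per-streamline termination label sets.
#' @return Factor with levels \code{V1, V2, V3, excluded}.
#' @export
segment_hierarchy <- function(label_sets) {
  groups <- list(V1 = c("V1d", "V1v"), V2 = c("V2d", "V2v"),
                 V3 = c("V3d", "V3v"))
  out <- vapply(label_sets, function(s) {
    if (length(s) == 0) return("excluded")
    for (g in names(groups)) if (all(s %in% groups[[g]])) return(g)
    "excluded"
  }, character(1))
  factor(out, levels = c("V1", "V2", "V3", "excluded"))
}

#' Streamline counts and percentages per segment
#'
#' Percentages are taken over the scheme's non-excluded segments, so they
#' total 100 within a hemisphere.
#'
#' @param assignments Factor of per-streamline segment assignments
#'   (\code{excluded} level ignored for percentages).
#' @param hemisphere Optional hemisphere label attached to the rows.
#' @return Data frame with columns \code{hemisphere, segment, count,
#'   percent}.
#' @export
count_segments <- function(assignments, hemisphere = NA_character_) {
  lv <- setdiff(levels(assignments), "excluded")
  counts <- as.integer(table(factor(assignments, levels = lv)))
  total <- sum(counts)
  if (total == 0) stop("undefined percentage: no streamlines assigned")
  data.frame(hemisphere = hemisphere, segment = lv, count = counts,
             percent = 100 * counts / total)
}

#' Area-normalized streamline counts
#'
#' @param counts Named numeric vector of streamline counts per target
#'   region.
#' @param areas Named numeric vector of target surface areas (mm^2, > 0),
#'   covering the count names.
#' @return Counts per mm^2, streamlines/mm^2.
#' @export
normalize_by_area <- function(counts, areas) {
  if (any(areas[names(counts)] <= 0) || any(!names(counts) %in% names(areas)))
    stop("every count needs a positive matching area")
  counts / areas[names(counts)]
}

#' Control-region false-positive ratio
#'
#' Ratio of streamlines terminating in the control region (V3A) to those
#' terminating in areas V1, V2 or V3, optionally also per unit target
#' surface area.
#'
#' @param counts Named counts including \code{V1, V2, V3} and the control
#'   entry.
#' @param control Name of the control region entry.
#' @param areas Optional named areas; when given, the area-normalized
#'   variant is also returned.
#' @return List with \code{ratio} and (when areas are given)
#'   \code{ratio_area_normalized}.
#' @export
false_positive_rate <- function(counts, control = "V3A", areas = NULL) {
  denom <- sum(counts[c("V1", "V2", "V3")])
  if (!is.finite(denom) || denom <= 0)
    stop("V1+V2+V3 streamline count must be positive")
  out <- list(ratio = unname(counts[control] / denom))
  if (!is.null(areas)) {
    nc <- normalize_by_area(counts, areas)
    out$ratio_area_normalized <- unname(nc[control] /
                                          sum(nc[c("V1", "V2", "V3")]))
  }
  out
}
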