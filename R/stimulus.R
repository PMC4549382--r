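#' Stimulus configuration
#'
#' Parameters of the retinotopic mapping display: a wedge rotating in polar
#' angle and a ring sweeping eccentricity, both presented as apertures on a
#' discretized visual field, plus the volume timing. Defaults reproduce the
#' mapping protocol used throughout the package: a 10.40 degree radius field,
#' a 17.14 degree wedge stepping once per volume (21 volumes per revolution),
#' and a ring whose width scales logarithmically between 0.11 and 4.62
#' degrees over 15 volumes per revolution, with one aperture position per
#' 2.376 s volume.
#'
#' @param field_radius_deg Radius of the stimulated visual field (degrees).
#' @param wedge_width_deg Angular width of the wedge aperture (degrees).
#' @param wedge_vols_per_rev Volumes per wedge revolution.
#' @param ring_min_width_deg,ring_max_width_deg Ring width at the start and
#'   end of a revolution (degrees).
#' @param ring_vols_per_rev Volumes per ring revolution.
#' @param tr_s Volume repetition time (seconds).
#' @param grid_n Pixels per side of the square visual-field raster. Pixel
#'   centers span \code{[-R, R]} in each dimension.
#' @return An object of class \code{stimulus_config}.
#' @export
stimulus_config <- function(field_radius_deg = 10.40,
                            wedge_width_deg = 17.14,
                            wedge_vols_per_rev = 21L,
                            ring_min_width_deg = 0.11,
                            ring_max_width_deg = 4.62,
                            ring_vols_per_rev = 15L,
                            tr_s = 2.376,
                            grid_n = 101L) {
  stopifnot(field_radius_deg > 0,
            wedge_width_deg > 0, wedge_width_deg <= 360,
            ring_min_width_deg > 0,
            ring_min_width_deg < ring_max_width_deg,
            ring_max_width_deg <= 2 * field_radius_deg,
            wedge_vols_per_rev >= 1, ring_vols_per_rev >= 1,
            tr_s > 0, grid_n >= 16)
  structure(list(field_radius_deg = field_radius_deg,
                 wedge_width_deg = wedge_width_deg,
                 wedge_vols_per_rev = as.integer(wedge_vols_per_rev),
                 ring_min_width_deg = ring_min_width_deg,
                 ring_max_width_deg = ring_max_width_deg,
                 ring_vols_per_rev = as.integer(ring_vols_per_rev),
                 tr_s = tr_s,
                 grid_n = as.integer(grid_n)),
            class = "stimulus_config")
}

#' Visual-field raster coordinates for a stimulus configuration
#'
#' @param cfg A \code{stimulus_config}.
#' @return List with vectors \code{x}, \code{y} (pixel-center coordinates in
#'   degrees), matrices \code{xx}, \code{yy}, and logical matrix \code{disk}
#'   marking pixels inside the stimulated field.
#' @keywords internal
field_grid <- function(cfg) {
  co <- seq(-cfg$field_radius_deg, cfg$field_radius_deg,
            length.out = cfg$grid_n)
  xx <- matrix(co, cfg$grid_n, cfg$grid_n)
  yy <- t(xx)
  list(x = co, y = co, xx = xx, yy = yy,
       disk = xx^2 + yy^2 <= cfg$field_radius_deg^2)
}

new_aperture_sequence <- function(masks, times, cfg) {
  stopifnot(length(dim(masks)) == 3, dim(masks)[1] == length(times))
  structure(list(masks = masks, times = times, cfg = cfg),
            class = "aperture_sequence")
}

#' @export
print.aperture_sequence <- function(x, ...) {
  cat(sprintf("Aperture sequence: %d volumes, %dx%d raster, field radius %.2f deg\n",
              dim(x$masks)[1], dim(x$masks)[2], dim(x$masks)[3],
              x$cfg$field_radius_deg))
  invisible(x)
}

#' Rotating-wedge aperture sequence
#'
#' One revolution advances the wedge by \code{360 / wedge_vols_per_rev}
#' degrees per volume; the wedge starts on the right horizontal meridian and
#' angles are measured counter-clockwise.
#'
#' @param cfg A \code{stimulus_config}.
#' @param n_rev Number of revolutions (>= 1).
#' @param direction \code{"cw"} or \code{"ccw"}.
#' @return An \code{aperture_sequence} of \code{n_rev * wedge_vols_per_rev}
#'   binary masks.
#' @export
make_wedge_apertures <- function(cfg, n_rev, direction = c("cw", "ccw")) {
  direction <- match.arg(direction)
  if (n_rev < 1) stop("n_rev must be >= 1")
  g <- field_grid(cfg)
  n_vol <- n_rev * cfg$wedge_vols_per_rev
  step <- 360 / cfg$wedge_vols_per_rev
  sgn <- if (direction == "ccw") 1 else -1
  ang <- (atan2(g$yy, g$xx) * 180 / pi) %% 360
  masks <- array(0L, c(n_vol, cfg$grid_n, cfg$grid_n))
  for (k in seq_len(n_vol)) {
    start <- (sgn * (k - 1) * step) %% 360
    rel <- (ang - start) %% 360
    masks[k, , ] <- as.integer(g$disk & rel < cfg$wedge_width_deg)
  }
  new_aperture_sequence(masks, (seq_len(n_vol) - 1) * cfg$tr_s, cfg)
}

#' Ring width sequence for one revolution
#'
#' Widths are log-spaced from the configured minimum to maximum across one
#' revolution; inner radii advance with the width sequence so that the ring
#' sweeps from fixation (inner radius 0) to the field edge (outer radius R)
#' within each revolution.
#'
#' @param cfg A \code{stimulus_config}.
#' @return Data frame with columns \code{width}, \code{inner}, \code{outer}
#'   (degrees), one row per volume of a revolution.
#' @export
ring_width_schedule <- function(cfg) {
  n <- cfg$ring_vols_per_rev
  wmin <- cfg$ring_min_width_deg
  wmax <- cfg$ring_max_width_deg
  w <- exp(seq(log(wmin), log(wmax), length.out = n))
  inner <- (cfg$field_radius_deg - w) * (w - wmin) / (wmax - wmin)
  data.frame(width = w, inner = inner, outer = inner + w)
}

#' Expanding/contracting ring aperture sequence
#'
#' @param cfg A \code{stimulus_config}.
#' @param n_rev Number of revolutions (>= 1).
#' @param direction \code{"expand"} or \code{"contract"}; the contracting
#'   sequence is the volume-reversed expanding sequence.
#' @return An \code{aperture_sequence} of \code{n_rev * ring_vols_per_rev}
#'   masks.
#' @export
make_ring_apertures <- function(cfg, n_rev, direction = c("expand", "contract")) {
  direction <- match.arg(direction)
  if (n_rev < 1) stop("n_rev must be >= 1")
  if (cfg$ring_min_width_deg >= cfg$ring_max_width_deg)
    stop("ring min width must be < max width")
  g <- field_grid(cfg)
  sched <- ring_width_schedule(cfg)
  if (direction == "contract") sched <- sched[rev(seq_len(nrow(sched))), ]
  rr <- sqrt(g$xx^2 + g$yy^2)
  n <- cfg$ring_vols_per_rev
  n_vol <- n_rev * n
  masks <- array(0L, c(n_vol, cfg$grid_n, cfg$grid_n))
  for (k in seq_len(n_vol)) {
    i <- ((k - 1) %% n) + 1
    masks[k, , ] <- as.integer(g$disk & rr >= sched$inner[i] &
                                 rr < sched$outer[i])
  }
  new_aperture_sequence(masks, (seq_len(n_vol) - 1) * cfg$tr_s, cfg)
}

#' Photic-burst run schedule
#'
#' Each run presents the full-field stimulus for \code{stim_vols} volumes
#' followed by \code{rest_vols} volumes of mean luminance. The default
#' protocol (10 runs of 1 + 14 volumes) totals 150 volumes.
#'
#' @param n_runs,stim_vols,rest_vols Non-negative counts.
#' @return A \code{run_schedule}: per-volume condition labels
#'   (\code{"stimulus"}/\code{"blank"}) and run boundaries.
#' @export
make_burst_schedule <- function(n_runs = 10L, stim_vols = 1L, rest_vols = 14L) {
  stopifnot(n_runs >= 0, stim_vols >= 0, rest_vols >= 0)
  per_run <- c(rep("stimulus", stim_vols), rep("blank", rest_vols))
  labels <- rep(per_run, times = n_runs)
  structure(list(labels = labels,
                 run_starts = if (n_runs > 0)
                   seq(1L, by = length(per_run), length.out = n_runs)
                 else integer(0),
                 n_runs = as.integer(n_runs)),
            class = "run_schedule")
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf("Run schedule: %d volumes (%d stimulus) in %d run(s)\n",
              length(x$labels), sum(x$labels == "stimulus"), x$n_runs))
  invisible(x)
}

#' Combined wedge + ring mapping run
#'
#' The wedge and ring cycle simultaneously at independent frequencies; the
#' per-volume aperture is the union of the two masks. A block of blank
#' (mean-luminance, all-zero) volumes is appended. The stimulation lengths
#' must agree: \code{wedge_revs * wedge_vols_per_rev} must equal
#' \code{ring_revs * ring_vols_per_rev}.
#'
#' @param cfg A \code{stimulus_config}.
#' @param wedge_revs,ring_revs Revolutions of each aperture.
#' @param blank_vols Blank volumes appended after stimulation.
#' @param wedge_direction,ring_direction Motion directions.
#' @return List with the combined \code{aperture_sequence} and the
#'   \code{run_schedule} (stimulus labels then blanks).
#' @export
make_mapping_run <- function(cfg, wedge_revs = 10L, ring_revs = 14L,
                             blank_vols = 24L,
                             wedge_direction = "cw",
                             ring_direction = "expand") {
  n_stim <- wedge_revs * cfg$wedge_vols_per_rev
  if (n_stim != ring_revs * cfg$ring_vols_per_rev)
    stop("wedge and ring stimulation lengths differ: ",
         n_stim, " vs ", ring_revs * cfg$ring_vols_per_rev)
  wedge <- make_wedge_apertures(cfg, wedge_revs, wedge_direction)
  ring <- make_ring_apertures(cfg, ring_revs, ring_direction)
  n_tot <- n_stim + blank_vols
  masks <- array(0L, c(n_tot, cfg$grid_n, cfg$grid_n))
  masks[seq_len(n_stim), , ] <- pmax(wedge$masks, ring$masks)
  ap <- new_aperture_sequence(masks, (seq_len(n_tot) - 1) * cfg$tr_s, cfg)
  labels <- c(rep("stimulus", n_stim), rep("blank", blank_vols))
  sched <- structure(list(labels = labels, run_starts = 1L, n_runs = 1L),
                     class = "run_schedule")
  list(apertures = ap, schedule = sched)
}

#' Write an aperture sequence as a NIfTI volume (T x X x Y)
#'
#' @param ap An \code{aperture_sequence}.
#' @param path Output file path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_apertures_nifti <- function(ap, path) {
  RNifti::writeNifti(ap$masks, path)
  invisible(path)
}
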