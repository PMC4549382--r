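#' Hemodynamic response function parameters
#'
#' Difference-of-gammas HRF. Each gamma component is parameterized by its
#' delay (the mean of the gamma density, seconds) and dispersion (the scale,
#' seconds); the undershoot is subtracted with weight \code{1/ratio}. The
#' density mode sits at \code{delay - dispersion}.
#'
#' @param peak_delay_s,undershoot_delay_s Component delays (s).
#' @param peak_dispersion_s,undershoot_dispersion_s Component dispersions (s).
#' @param peak_undershoot_ratio Positive ratio of peak to undershoot
#'   amplitude.
#' @param length_s Kernel support (s).
#' @return An object of class \code{hrf_params}.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                       peak_undershoot_ratio = 6, length_s = 32) {
  stopifnot(peak_delay_s > 0, undershoot_delay_s > 0,
            peak_dispersion_s > 0, undershoot_dispersion_s > 0,
            peak_undershoot_ratio > 0, length_s > 0)
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion_s = peak_dispersion_s,
                 undershoot_dispersion_s = undershoot_dispersion_s,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 length_s = length_s),
            class = "hrf_params")
}

#' Sampled double-gamma HRF kernel
#'
#' \code{kernel(t) = g(t; peak) - g(t; undershoot)/ratio}, with each
#' \code{g} a gamma density of shape \code{delay/dispersion} and scale
#' \code{dispersion}, sampled every \code{tr_s} seconds from 0 to
#' \code{duration_s} and normalized to unit peak.
#'
#' @param h An \code{hrf_params}.
#' @param tr_s Sampling interval (s).
#' @param duration_s Kernel length (s); must cover the peak delay.
#' @return Numeric vector of kernel samples with attribute \code{"times"}.
#' @export
double_gamma_kernel <- function(h, tr_s, duration_s = h$length_s) {
  if (h$peak_dispersion_s <= 0 || h$undershoot_dispersion_s <= 0)
    stop("dispersions must be positive")
  if (duration_s < h$peak_delay_s)
    stop("duration_s must cover the peak delay")
  t <- seq(0, duration_s, by = tr_s)
  k <- stats::dgamma(t, shape = h$peak_delay_s / h$peak_dispersion_s,
                     scale = h$peak_dispersion_s) -
    stats::dgamma(t, shape = h$undershoot_delay_s / h$undershoot_dispersion_s,
                  scale = h$undershoot_dispersion_s) / h$peak_undershoot_ratio
  k <- k / max(k)
  attr(k, "times") <- t
  k
}

# onsets of stimulus blocks in a run schedule
event_onsets <- function(sched) {
  stim <- sched$labels == "stimulus"
  which(stim & !c(FALSE, stim[-length(stim)]))
}

#' Estimate the HRF from photic-burst responses
#'
#' Extracts the event-locked average response to brief full-field stimulation
#' and fits the double-gamma kernel by Nelder-Mead least squares over the
#' peak delay, undershoot delay and peak/undershoot ratio, with both
#' dispersions held fixed. Amplitude and offset are profiled out linearly at
#' each objective evaluation.
#'
#' @param series Numeric BOLD series (one voxel/vertex, or the average over
#'   responsive ones).
#' @param sched A \code{run_schedule} with at least one stimulus event.
#' @param tr_s Sampling interval (s).
#' @param init Starting \code{hrf_params}.
#' @param r2_floor Fits with variance explained below this floor are flagged
#'   degenerate.
#' @return An \code{hrf_params} with extra fields \code{r2},
#'   \code{amplitude}, \code{degenerate} and \code{epoch_mean}.
#' @export
fit_hrf <- function(series, sched, tr_s, init = hrf_params(),
                    r2_floor = 0.5) {
  onsets <- event_onsets(sched)
  if (length(onsets) == 0) stop("schedule contains no stimulus events")
  if (length(series) != length(sched$labels))
    stop("series length does not match schedule")
  if (stats::sd(series) == 0) stop("degenerate fit: constant series")
  epoch_len <- if (length(onsets) > 1) min(diff(onsets)) else
    length(series) - onsets[1] + 1
  epochs <- vapply(onsets[onsets + epoch_len - 1 <= length(series)],
                   function(o) series[o:(o + epoch_len - 1)],
                   numeric(epoch_len))
  y <- rowMeans(epochs)

  dur <- (epoch_len - 1) * tr_s
  obj <- function(par) {
    pd <- par[1]; ud <- par[2]; ratio <- exp(par[3])
    if (pd <= 0 || ud <= 0 || pd > dur || !is.finite(ratio)) return(1e6)
    h <- hrf_params(pd, ud, init$peak_dispersion_s,
                    init$undershoot_dispersion_s, ratio,
                    length_s = max(pd, dur, 1))
    k <- double_gamma_kernel(h, tr_s, dur)
    if (any(!is.finite(k))) return(1e6)
    fit <- stats::lm.fit(cbind(1, k), y)
    sum(fit$residuals^2)
  }
  par0 <- c(init$peak_delay_s, init$undershoot_delay_s,
            log(init$peak_undershoot_ratio))
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  h <- hrf_params(opt$par[1], opt$par[2], init$peak_dispersion_s,
                  init$undershoot_dispersion_s, exp(opt$par[3]),
                  length_s = init$length_s)
  k <- double_gamma_kernel(h, tr_s, (epoch_len - 1) * tr_s)
  fit <- stats::lm.fit(cbind(1, k), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  h$r2 <- r2
  h$amplitude <- unname(fit$coefficients[2])
  h$degenerate <- !is.finite(r2) || r2 < r2_floor
  h$epoch_mean <- y
  h
}
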