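# Step detection from vertical lower-trunk acceleration, and the
# temporospatial gait variables.

# Peak prominence: height above the higher of the two minima separating
# the peak from the nearest higher sample on each side (or the signal edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    higher_left <- which(x[seq_len(p - 1)] > x[p])
    lo <- if (length(higher_left)) max(higher_left) + 1L else 1L
    higher_right <- which(x[seq(p + 1, length(x))] > x[p])
    hi <- if (length(higher_right)) p + min(higher_right) - 1L else length(x)
    left_min <- min(x[lo:p])
    right_min <- min(x[p:hi])
    x[p] - max(left_min, right_min)
  }, numeric(1))
}

# Dominant frequency of a signal within [f_lo, f_hi] Hz via the
# periodogram. Returns NA when no bin in the band dominates the band's
# median power by at least `dominance` (flat/noise spectra).
dominant_frequency <- function(x, fs, f_lo = 0.5, f_hi = 4, dominance = 10) {
  x <- x - mean(x)
  n <- length(x)
  if (n < 8 || all(abs(x) < 1e-15)) return(NA_real_)
  pw <- Mod(stats::fft(x)[seq_len(floor(n / 2) + 1)])^2
  freqs <- (seq_along(pw) - 1) * fs / n
  band <- which(freqs >= f_lo & freqs <= f_hi)
  if (length(band) < 3) return(NA_real_)
  pk <- band[which.max(pw[band])]
  med <- stats::median(pw[band])
  if (med <= 0 || pw[pk] < dominance * med) return(NA_real_)
  freqs[pk]
}

#' Detect steps from vertical lower-trunk acceleration
#'
#' Gait cycles are read off the vertical (VT) lower-trunk acceleration:
#' each step produces one VT peak. The step period is first estimated from
#' the dominant frequency of the VT spectrum in 0.5-4 Hz; local maxima are
#' then kept if their prominence is at least `prominence_frac` times the
#' signal SD and their height at least `height_frac` times the signal SD
#' (step peaks of the gravity-free VT axis are positive; noise blips in
#' the inter-step valleys are not), and finally thinned to a minimum
#' separation of `min_sep_frac` step periods (larger peaks win).
#'
#' @param trial A preprocessed (`gravity_removed`, `filtered`) lower-trunk
#'   trial.
#' @param prominence_frac Prominence threshold as a fraction of SD(VT),
#'   default 0.3.
#' @param min_sep_frac Minimum peak separation as a fraction of the
#'   estimated step period, default 0.5.
#' @param height_frac Minimum peak height as a fraction of SD(VT),
#'   default 0.3.
#' @return A `gait_events` object: `peak_indices` (1-based sample
#'   indices), `step_times` (s), `step_durations` (successive-peak
#'   intervals, s), `stride_durations` (alternate-peak intervals, s),
#'   `step_frequency` (Hz), `sampling_rate`.
#' @export
detect_steps <- function(trial, prominence_frac = 0.3, min_sep_frac = 0.5,
                         height_frac = 0.3) {
  stopifnot(inherits(trial, "raw_trial"))
  assert_that(isTRUE(trial$gravity_removed) && isTRUE(trial$filtered),
              "trial must be gravity-removed and filtered before step detection")
  x <- trial$acc$acc_vt_g
  fs <- trial$sampling_rate

  step_freq <- dominant_frequency(x, fs, 0.5, 4)
  if (is.na(step_freq)) stopf("no gait detected: no dominant frequency in 0.5-4 Hz")

  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) == 0) stopf("no gait detected: no local maxima")
  sdx <- stats::sd(x)
  cand <- cand[x[cand] >= height_frac * sdx]
  if (length(cand) == 0) stopf("fewer than 4 step peaks detected")
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= prominence_frac * sdx]
  if (length(cand) < 4) stopf("fewer than 4 step peaks detected")

  # Greedy non-maximum suppression at the minimum separation.
  min_sep <- min_sep_frac * fs / step_freq
  keep <- integer(0)
  for (p in cand[order(x[cand], decreasing = TRUE)]) {
    if (all(abs(p - keep) >= min_sep)) keep <- c(keep, p)
  }
  peaks <- sort(keep)
  if (length(peaks) < 4) stopf("fewer than 4 step peaks detected")

  step_times <- trial$acc$time_s[peaks]
  structure(list(
    peak_indices = peaks,
    step_times = step_times,
    step_durations = diff(step_times),
    stride_durations = diff(step_times, lag = 2),
    step_frequency = step_freq,
    sampling_rate = fs
  ), class = "gait_events")
}

#' Restrict gait events to a time window
#'
#' Used to limit events to the timed middle 10 m of a trial before
#' computing step counts.
#'
#' @param events A `gait_events` object.
#' @param t_start,t_end Window bounds in seconds (inclusive).
#' @return A `gait_events` object over the window.
#' @export
clip_events <- function(events, t_start, t_end) {
  stopifnot(inherits(events, "gait_events"))
  sel <- events$step_times >= t_start & events$step_times <= t_end
  st <- events$step_times[sel]
  structure(list(
    peak_indices = events$peak_indices[sel],
    step_times = st,
    step_durations = diff(st),
    stride_durations = diff(st, lag = 2),
    step_frequency = events$step_frequency,
    sampling_rate = events$sampling_rate
  ), class = "gait_events")
}

#' Temporospatial gait variables from detected steps
#'
#' Walking speed is the timed distance over the timed duration; step
#' length is the distance divided by the number of steps; cadence is the
#' number of steps per minute of the timed duration; step-timing
#' variability is the sample SD of successive gait-cycle durations, where
#' a gait cycle is by default the stride (alternate-peak interval); the
#' successive step-interval reading is available via `cycle = "step"`.
#'
#' @param events `gait_events` covering the timed segment.
#' @param timed_duration Timed duration in seconds.
#' @param distance Timed distance in metres (default 10).
#' @param cycle `"stride"` (default) or `"step"`: interval used for the
#'   timing-variability SD.
#' @return A list: `walking_speed` (m/s), `step_length` (cm), `cadence`
#'   (steps/min), `step_timing_variability` (s), `n_steps`.
#' @export
temporospatial <- function(events, timed_duration, distance = 10,
                           cycle = c("stride", "step")) {
  stopifnot(inherits(events, "gait_events"))
  cycle <- match.arg(cycle)
  n_steps <- length(events$peak_indices)
  assert_that(n_steps > 0, "no steps in events")
  assert_that(timed_duration > 0, "timed_duration must be > 0")
  cyc <- if (cycle == "stride") events$stride_durations else
    events$step_durations
  list(
    walking_speed = distance / timed_duration,
    step_length = 100 * distance / n_steps,
    cadence = 60 * n_steps / timed_duration,
    step_timing_variability = sd_or_zero(cyc),
    n_steps = n_steps
  )
}
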