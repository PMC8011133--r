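# Preprocessing: gravity removal, zero-phase low-pass filtering, and the
# trial-set validity rule.

axis_cols <- c("acc_ml_g", "acc_ap_g", "acc_vt_g")

#' Remove the gravity component from a trial
#'
#' Subtracts the per-axis mean over the analysed segment, which removes the
#' +1 g static offset from the VT axis of an upright, calibrated sensor and
#' centres all axes at zero. Attitude estimation is deliberately out of
#' scope: mean subtraction is the minimal interpretation consistent with
#' static plus/minus 1 g calibration.
#'
#' @param trial A `raw_trial`.
#' @return The trial with zero-mean axes and `gravity_removed = TRUE`.
#' @export
remove_gravity <- function(trial) {
  stopifnot(inherits(trial, "raw_trial"))
  assert_that(nrow(trial$acc) > 0, "empty signal")
  for (col in axis_cols) {
    trial$acc[[col]] <- trial$acc[[col]] - mean(trial$acc[[col]])
  }
  trial$gravity_removed <- TRUE
  trial
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an `order`-th order Butterworth low-pass forward and backward
#' (`signal::filtfilt`), giving zero phase distortion — peak timing is
#' preserved for step detection — at the cost of squaring the magnitude
#' response, so the effective attenuation is that of a filter of twice the
#' nominal order. DC gain is 1.
#'
#' @param trial A `raw_trial` (typically after [remove_gravity()]).
#' @param order Filter order (default 2).
#' @param cutoff Cutoff frequency in Hz (default 22); must be below
#'   Nyquist.
#' @return The filtered trial with `filtered = TRUE`.
#' @export
lowpass <- function(trial, order = 2, cutoff = 22) {
  stopifnot(inherits(trial, "raw_trial"))
  nyq <- trial$sampling_rate / 2
  assert_that(cutoff < nyq,
              "cutoff %g Hz must be below Nyquist (%g Hz)", cutoff, nyq)
  assert_that(nrow(trial$acc) > 3 * order + 1,
              "signal too short to filter")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  for (col in axis_cols) {
    # Filter around the mean and re-centre afterwards: the DC component
    # passes with gain exactly 1 and no start-up transient, so filtering
    # and mean (gravity) removal commute to machine precision.
    x <- trial$acc[[col]]
    m <- mean(x)
    y <- as.numeric(signal::filtfilt(bf, x - m))
    trial$acc[[col]] <- y - mean(y) + m
  }
  trial$filtered <- TRUE
  trial
}

#' Convenience wrapper: gravity removal then low-pass filtering
#'
#' @inheritParams lowpass
#' @return A clean trial ready for step detection and stability metrics.
#' @export
preprocess_trial <- function(trial, order = 2, cutoff = 22) {
  lowpass(remove_gravity(trial), order = order, cutoff = cutoff)
}

#' Check a subject's trial set for timing consistency
#'
#' A subject's set of timed 10 m walk durations is invalid when their
#' coefficient of variation (population SD divided by mean) exceeds 5%:
#' the subject did not walk at a consistent self-selected pace across
#' trials.
#'
#' @param durations Numeric vector of at least two timed durations (s).
#' @return `"valid"` or `"invalid"`, with the CV attached as attribute
#'   `cv`.
#' @export
check_trial_set_validity <- function(durations) {
  assert_that(length(durations) >= 2, "need at least 2 durations")
  assert_that(all(is.finite(durations)) && all(durations > 0),
              "durations must be positive and finite")
  n <- length(durations)
  cv <- stats::sd(durations) * sqrt((n - 1) / n) / mean(durations)
  structure(if (cv > 0.05) "invalid" else "valid", cv = cv)
}
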