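# Assembly of the full per-trial and per-subject gait feature vector:
# 5 temporospatial variables + 6 stability metrics x 3 axes x 2 sensors.

stability_metric_names <- c("rms", "hr", "sr1", "sr2", "symmetry",
                            "variability")
feature_axes <- c("vt", "ml", "ap")
feature_sites <- c(trunk = "lower_trunk", head = "head")

#' Canonical names of the 41 gait features
#'
#' Five temporospatial variables followed by `<site>_<axis>_<metric>` for
#' site in `trunk`/`head`, axis in `vt`/`ml`/`ap`, metric in `rms`, `hr`,
#' `sr1`, `sr2`, `symmetry`, `variability`. Ordering is stable.
#'
#' @return Character vector of length 41.
#' @export
gait_feature_names <- function() {
  c("walking_speed", "step_length", "cadence", "step_timing_variability",
    "n_steps",
    as.vector(t(outer(names(feature_sites), as.vector(t(outer(
      feature_axes, stability_metric_names, paste, sep = "_"))),
      paste, sep = "_"))))
}

axis_signal <- function(trial, axis) {
  trial$acc[[paste0("acc_", axis, "_g")]]
}

#' Compute all gait variables for one head/lower-trunk trial pair
#'
#' Runs the full metric battery on a preprocessed trial pair: the five
#' temporospatial variables, then the six stability metrics on each of
#' the three axes of both sensors (36 values), using the stride frequency
#' derived from the lower-trunk gait events for both sensors (the two
#' record the same walk). Cadence and step-timing variability are
#' computed over the entire walking trial; walking speed, step length and
#' the step count come from the timed middle 10 m (events are clipped to
#' a central window of the timed duration).
#'
#' Any metric that fails on its input (for example a degenerate harmonic
#' denominator, or no dominant spectral peak) is reported as `NA` and
#' listed in the `flags` attribute; a failure never silently drops the
#' remaining metrics.
#'
#' @param head,trunk Preprocessed `raw_trial`s from the head and lower
#'   trunk.
#' @param events `gait_events` detected on the lower-trunk VT axis.
#' @param n_harmonics,hr_ml_inverted Passed to [harmonic_ratio()].
#' @param window_strides Passed to [gait_variability()].
#' @param cycle Interval definition for timing variability, see
#'   [temporospatial()].
#' @return Named numeric vector of the 41 features (see
#'   [gait_feature_names()]), with attribute `flags` naming failed
#'   metrics.
#' @export
compute_all <- function(head, trunk, events, n_harmonics = 20,
                        hr_ml_inverted = TRUE, window_strides = 4,
                        cycle = "stride") {
  stopifnot(inherits(events, "gait_events"))
  for (tr in list(head, trunk)) {
    assert_that(isTRUE(tr$gravity_removed) && isTRUE(tr$filtered),
                "trials must be preprocessed before feature extraction")
  }
  assert_that(head$sensor_site == "head" && trunk$sensor_site == "lower_trunk",
              "pass the head trial first and the lower-trunk trial second")

  fs <- trunk$sampling_rate
  total_dur <- nrow(trunk$acc) / fs
  f0 <- estimate_stride_frequency(events = events)

  # timed middle 10 m: central window of the timed duration
  td <- min(trunk$timed_duration, total_dur)
  mid <- total_dur / 2
  timed_ev <- clip_events(events, mid - td / 2, mid + td / 2)

  flags <- character(0)
  out <- stats::setNames(rep(NA_real_, length(gait_feature_names())),
                         gait_feature_names())

  ts_timed <- tryCatch(temporospatial(timed_ev, td, trunk$walkway_distance,
                                      cycle = cycle),
                       error = function(e) NULL)
  ts_full <- temporospatial(events, total_dur, cycle = cycle)
  out["walking_speed"] <- trunk$walkway_distance / trunk$timed_duration
  out["cadence"] <- ts_full$cadence
  out["step_timing_variability"] <- ts_full$step_timing_variability
  if (!is.null(ts_timed)) {
    out["step_length"] <- ts_timed$step_length
    out["n_steps"] <- ts_timed$n_steps
  } else {
    flags <- c(flags, "step_length", "n_steps")
  }

  trials <- list(trunk = trunk, head = head)
  for (site in names(trials)) {
    tr <- trials[[site]]
    for (axis in feature_axes) {
      x <- axis_signal(tr, axis)
      key <- function(m) paste(site, axis, m, sep = "_")
      set_metric <- function(m, expr) {
        v <- tryCatch(suppressWarnings(as.numeric(expr())),
                      error = function(e) NA_real_)
        if (length(v) != 1 || !is.finite(v)) {
          flags <<- c(flags, key(m))
          v <- NA_real_
        }
        out[key(m)] <<- v
      }
      set_metric("rms", function() acc_rms(x))
      set_metric("hr", function()
        harmonic_ratio(x, fs, f0, n_harmonics, axis, hr_ml_inverted))
      reg <- tryCatch(autocorr_regularity(x, fs, f0),
                      error = function(e) NULL)
      if (is.null(reg)) {
        flags <- c(flags, key("sr1"), key("sr2"), key("symmetry"))
      } else {
        out[key("sr1")] <- reg$sr1
        out[key("sr2")] <- reg$sr2
        set_metric("symmetry", function() gait_symmetry(reg$sr1, reg$sr2))
      }
      set_metric("variability", function()
        gait_variability(x, fs, f0, window_strides))
    }
  }
  attr(out, "flags") <- unique(flags)
  out
}

#' Extract averaged features for one simulated subject
#'
#' Preprocesses every trial pair, detects steps on the lower-trunk VT
#' axis, computes the 41 features per trial and averages them across the
#' subject's trials (missing values are dropped per feature). The
#' subject's timed durations are screened with
#' [check_trial_set_validity()].
#'
#' @param subject A subject record from [simulate_cohort()].
#' @param ... Passed to [compute_all()].
#' @return Named numeric feature vector with attributes `validity` and
#'   `flags`.
#' @export
subject_features <- function(subject, ...) {
  durations <- vapply(subject$trials,
                      function(tp) tp$lower_trunk$timed_duration, numeric(1))
  validity <- if (length(durations) >= 2) {
    check_trial_set_validity(durations)
  } else {
    "valid"
  }
  rows <- lapply(subject$trials, function(tp) {
    trunk <- preprocess_trial(tp$lower_trunk)
    head <- preprocess_trial(tp$head)
    events <- detect_steps(trunk)
    compute_all(head, trunk, events, ...)
  })
  mat <- do.call(rbind, rows)
  feats <- colMeans(mat, na.rm = TRUE)
  feats[is.nan(feats)] <- NA_real_
  structure(feats,
            validity = as.character(validity),
            flags = unique(unlist(lapply(rows, attr, "flags"))))
}

#' Build the cohort feature table
#'
#' One row per subject: `subject_id`, `group` (severity label), `cohort`
#' (`healthy`/`bppv`), `dhi`, demographics, then the 41 gait features.
#' Subjects whose timed durations fail the 5% consistency rule are
#' dropped with a warning.
#'
#' @param subjects List of subject records from [simulate_cohort()].
#' @param ... Passed to [compute_all()].
#' @return A data.frame feature table.
#' @export
cohort_features <- function(subjects, ...) {
  rows <- lapply(subjects, function(s) {
    f <- subject_features(s, ...)
    if (attr(f, "validity") == "invalid") {
      warning(sprintf("subject %s dropped: trial durations inconsistent (>5%% CV)",
                      s$subject_id), call. = FALSE)
      return(NULL)
    }
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     cohort = s$cohort, dhi = s$dhi, age = s$age,
                     sex = s$sex, height = s$height, weight = s$weight,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f)))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
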