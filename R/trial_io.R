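# Trial container and CSV/JSON interchange.

#' Construct a raw walking trial
#'
#' @param subject_id Subject identifier.
#' @param sensor_site `"head"` or `"lower_trunk"`.
#' @param sampling_rate Sampling rate in Hz (> 44).
#' @param acc Data frame with columns `time_s, acc_ml_g, acc_ap_g,
#'   acc_vt_g` (acceleration in g; ML = X right, AP = Y forward, VT = Z up).
#' @param timed_duration Timed walking duration over the middle 10 m, s.
#' @param walkway_distance Timed distance in metres (fixed 10).
#' @return A `raw_trial` object.
#' @export
new_raw_trial <- function(subject_id, sensor_site, sampling_rate, acc,
                          timed_duration, walkway_distance = 10) {
  assert_that(sensor_site %in% c("head", "lower_trunk"),
              "sensor_site must be 'head' or 'lower_trunk'")
  assert_that(sampling_rate > 44, "sampling_rate must exceed 44 Hz")
  assert_that(is.data.frame(acc) &&
                all(c("time_s", "acc_ml_g", "acc_ap_g", "acc_vt_g") %in%
                      names(acc)),
              "acc must have columns time_s, acc_ml_g, acc_ap_g, acc_vt_g")
  assert_that(nrow(acc) > 0 && all(vapply(acc, function(x) all(is.finite(x)),
                                          logical(1))),
              "all acceleration samples must be finite")
  assert_that(timed_duration > 0, "timed_duration must be > 0")
  structure(list(
    subject_id = subject_id,
    sensor_site = sensor_site,
    sampling_rate = sampling_rate,
    acc = acc,
    timed_duration = timed_duration,
    walkway_distance = walkway_distance,
    gravity_removed = FALSE,
    filtered = FALSE
  ), class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf(
    "<%s trial> subject %s, %s, %d samples @ %g Hz (%.1f s), timed 10 m: %.2f s\n",
    if (isTRUE(x$filtered)) "clean" else "raw",
    x$subject_id, x$sensor_site, nrow(x$acc), x$sampling_rate,
    nrow(x$acc) / x$sampling_rate, x$timed_duration))
  invisible(x)
}

#' Write a trial as CSV plus a JSON metadata sidecar
#'
#' The CSV holds `time_s, acc_ml_g, acc_ap_g, acc_vt_g`; the sidecar
#' (`<path>.json`) holds subject id, sensor site, sampling rate and the
#' timed 10 m duration.
#'
#' @param trial A `raw_trial`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "raw_trial"))
  utils::write.csv(trial$acc, path, row.names = FALSE)
  meta <- list(subject_id = trial$subject_id,
               sensor_site = trial$sensor_site,
               sampling_rate = trial$sampling_rate,
               timed_duration = trial$timed_duration,
               walkway_distance = trial$walkway_distance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial from CSV plus its JSON sidecar
#'
#' Accepts the dialect written by [write_trial_csv()]; real sensor exports
#' in the same column layout load identically.
#'
#' @param path CSV path; metadata is read from `<path>.json`.
#' @return A `raw_trial`.
#' @export
read_trial_csv <- function(path) {
  acc <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  assert_that(file.exists(meta_path), "metadata sidecar %s not found",
              meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  new_raw_trial(meta$subject_id, meta$sensor_site, meta$sampling_rate, acc,
                meta$timed_duration, meta$walkway_distance %||% 10)
}
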