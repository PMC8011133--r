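# The six walking-stability metrics: RMS, harmonic ratio, step/stride
# regularity from the unbiased autocorrelation, gait symmetry, and
# spectral gait variability (dominant-peak FWHM).

#' Root mean square of an acceleration signal
#'
#' Dispersion of the (gravity-free) acceleration about zero:
#' `sqrt(mean(x^2))`. For a zero-mean signal this equals the population
#' SD.
#'
#' @param x Numeric signal in g.
#' @return RMS in g.
#' @export
acc_rms <- function(x) {
  assert_that(length(x) > 0, "empty signal")
  sqrt(mean(x^2))
}

#' Unbiased normalized autocorrelation
#'
#' The unbiased autocovariance `sum(x[t] * x[t + lag]) / (n - lag)` of the
#' mean-centred signal, normalized by the lag-0 value so the coefficient
#' at lag 0 is 1. Computed via FFT; identical to the O(n^2) definition.
#'
#' @param x Numeric signal.
#' @param max_lag Largest lag (samples) to return.
#' @return Numeric vector of coefficients for lags `0..max_lag`.
#' @export
unbiased_autocorr <- function(x, max_lag = length(x) - 1L) {
  n <- length(x)
  assert_that(n >= 2, "signal too short for autocorrelation")
  assert_that(max_lag >= 1 && max_lag <= n - 1,
              "max_lag must be in [1, n - 1]")
  x <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  s <- Re(stats::fft(Mod(stats::fft(c(x, numeric(npad - n))))^2,
                     inverse = TRUE)) / npad
  lags <- 0:max_lag
  acov <- s[lags + 1] / (n - lags)
  if (acov[1] < 1e-300) stopf("zero-variance signal")
  acov / acov[1]
}

#' Estimate the stride frequency of a gait signal
#'
#' With detected gait events, the stride frequency is the reciprocal of
#' the mean stride duration. Without events, it is estimated from the lag
#' of the largest unbiased-autocorrelation peak with the stride period
#' searched in 0.5-4 s (stride frequency 0.25-2 Hz). Note that for a
#' perfectly step-symmetric signal the step and stride lags are
#' indistinguishable by autocorrelation alone; the events-based estimate
#' resolves the ambiguity and is preferred whenever events exist.
#'
#' @param x Numeric signal (ignored when `events` is given).
#' @param fs Sampling rate, Hz.
#' @param events Optional `gait_events`.
#' @param min_coef Minimum autocorrelation coefficient for a credible
#'   periodicity (default 0.25); below it, an error is raised.
#' @return Stride frequency in Hz.
#' @export
estimate_stride_frequency <- function(x = NULL, fs = NULL, events = NULL,
                                      min_coef = 0.25) {
  if (!is.null(events)) {
    stopifnot(inherits(events, "gait_events"))
    assert_that(length(events$stride_durations) >= 1,
                "events carry no stride durations")
    return(1 / mean(events$stride_durations))
  }
  assert_that(!is.null(x) && !is.null(fs), "need a signal and sampling rate")
  lo <- max(2L, floor(0.5 * fs))
  hi <- min(length(x) - 1L, ceiling(4 * fs))
  assert_that(hi > lo + 2, "signal too short to estimate stride frequency")
  r <- unbiased_autocorr(x, hi)
  lags <- lo:hi
  coefs <- r[lags + 1]
  # local maxima within the search band
  is_peak <- c(FALSE, diff(sign(diff(coefs))) < 0, FALSE)
  if (!any(is_peak) || max(coefs[is_peak]) < min_coef) {
    stopf("no periodicity detected in the 0.25-2 Hz stride band")
  }
  best <- lags[is_peak][which.max(coefs[is_peak])]
  fs / best
}

#' Harmonic amplitudes at exact multiples of the stride frequency
#'
#' Evaluates the discrete Fourier amplitude `(2/n) |sum(x * exp(-2i pi f_k
#' t))|` at `f_k = k * stride_frequency`, `k = 1..n_harmonics`, after
#' trimming the signal to a whole number of strides (avoiding the spectral
#' leakage that would corrupt the even/odd separation).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param stride_frequency Stride (gait-cycle) frequency, Hz.
#' @param n_harmonics Number of harmonics (default 20). Harmonics at or
#'   above Nyquist are dropped.
#' @return Named numeric vector of amplitudes for harmonics `1..K`.
#' @export
harmonic_amplitudes <- function(x, fs, stride_frequency, n_harmonics = 20) {
  assert_that(stride_frequency > 0, "stride_frequency must be > 0")
  spp <- fs / stride_frequency                   # samples per stride
  n_strides <- floor(length(x) / spp)
  assert_that(n_strides >= 2, "signal shorter than 2 strides")
  n <- round(n_strides * spp)
  x <- x[seq_len(n)] - mean(x[seq_len(n)])
  ks <- seq_len(n_harmonics)
  ks <- ks[ks * stride_frequency < fs / 2]
  t <- (seq_len(n) - 1) / fs
  amps <- vapply(ks, function(k) {
    (2 / n) * Mod(sum(x * exp(-2i * pi * k * stride_frequency * t)))
  }, numeric(1))
  names(amps) <- paste0("h", ks)
  amps
}

#' Harmonic ratio of a gait acceleration axis
#'
#' The ratio of summed in-phase to out-of-phase stride-harmonic
#' amplitudes; higher values indicate smoother, more symmetric gait. For
#' the VT and AP axes the in-phase harmonics are the even ones (the step
#' frequency is twice the stride frequency), so HR = sum(even) /
#' sum(odd). The ML axis oscillates once per stride, so by the convention
#' of the harmonic-ratio literature its HR is inverted: sum(odd) /
#' sum(even). Set `hr_ml_inverted = FALSE` for the uniform even/odd
#' reading on all axes.
#'
#' @inheritParams harmonic_amplitudes
#' @param axis `"vt"`, `"ap"` or `"ml"`.
#' @param hr_ml_inverted Use the odd/even convention on ML (default TRUE).
#' @return The harmonic ratio, with attributes `orientation`
#'   (`"even/odd"` or `"odd/even"`) and, when the denominator vanishes
#'   while the numerator does not, `degenerate = TRUE` with value `Inf`.
#' @export
harmonic_ratio <- function(x, fs, stride_frequency, n_harmonics = 20,
                           axis = c("vt", "ap", "ml"),
                           hr_ml_inverted = TRUE) {
  axis <- match.arg(axis)
  amps <- harmonic_amplitudes(x, fs, stride_frequency, n_harmonics)
  ks <- as.integer(sub("^h", "", names(amps)))
  even <- sum(amps[ks %% 2 == 0])
  odd <- sum(amps[ks %% 2 == 1])
  inverted <- axis == "ml" && hr_ml_inverted
  num <- if (inverted) odd else even
  den <- if (inverted) even else odd
  orientation <- if (inverted) "odd/even" else "even/odd"
  if (den < 1e-12) {
    if (num < 1e-12) stopf("degenerate harmonic content")
    return(structure(Inf, orientation = orientation, degenerate = TRUE))
  }
  structure(num / den, orientation = orientation)
}

#' Step and stride regularity from the unbiased autocorrelation
#'
#' Step regularity (SR1) is the maximum unbiased autocorrelation
#' coefficient in a window of plus/minus 25% around the step lag (half
#' the stride period); stride regularity (SR2) the maximum around the
#' stride lag. Both are 1 for perfectly repeatable gait; SR1 drops below
#' SR2 when left and right steps differ.
#'
#' @inheritParams harmonic_amplitudes
#' @param window_frac Half-width of the lag search window as a fraction of
#'   the nominal lag (default 0.25).
#' @return List with elements `sr1` and `sr2`.
#' @export
autocorr_regularity <- function(x, fs, stride_frequency,
                                window_frac = 0.25) {
  assert_that(stride_frequency > 0, "stride_frequency must be > 0")
  stride_lag <- fs / stride_frequency
  step_lag <- stride_lag / 2
  hi <- ceiling(stride_lag * (1 + window_frac))
  assert_that(hi <= length(x) - 1,
              "lag window exceeds signal length")
  r <- unbiased_autocorr(x, hi)
  window_max <- function(lag) {
    lo <- max(1L, floor(lag * (1 - window_frac)))
    up <- min(hi, ceiling(lag * (1 + window_frac)))
    # the unbiased estimator can marginally exceed 1; the regularity
    # coefficient is defined on [-1, 1]
    min(1, max(-1, max(r[(lo:up) + 1])))
  }
  list(sr1 = window_max(step_lag), sr2 = window_max(stride_lag))
}

#' Gait symmetry from step and stride regularity
#'
#' Closeness of SR1/SR2 to 1, computed order-invariantly on absolute
#' values: `min(|SR1|, |SR2|) / max(|SR1|, |SR2|)`, in `[0, 1]`. The raw
#' ratio `SR1/SR2` is attached as attribute `raw_ratio`.
#'
#' @param sr1,sr2 Step and stride regularity coefficients.
#' @return Symmetry in `[0, 1]`.
#' @export
gait_symmetry <- function(sr1, sr2) {
  assert_that(is.finite(sr1) && is.finite(sr2), "SR1/SR2 must be finite")
  m <- max(abs(sr1), abs(sr2))
  assert_that(m >= 1e-12, "both regularities are zero")
  structure(min(abs(sr1), abs(sr2)) / m, raw_ratio = sr1 / sr2)
}

#' Welch power spectral density
#'
#' Mean-detrended, Hann-windowed, 50%-overlapping segment-averaged
#' one-sided PSD, scaled as a density so that `sum(psd) * df` equals the
#' signal variance (Parseval).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param n_window Segment length in samples.
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd` (signal units squared per Hz).
#' @export
welch_psd <- function(x, fs, n_window, overlap = 0.5) {
  n <- length(x)
  n_window <- min(as.integer(n_window), n)
  assert_that(n_window >= 8, "Welch window too short")
  step <- max(1L, floor(n_window * (1 - overlap)))
  starts <- seq(1L, n - n_window + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_window) / (n_window + 1))
  scale <- fs * sum(w^2)
  acc <- numeric(floor(n_window / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + n_window - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg)[seq_along(acc)])^2 / scale
    acc <- acc + p
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even windows)
  dbl <- seq_along(psd) > 1
  if (n_window %% 2 == 0) dbl[length(psd)] <- FALSE
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_along(psd) - 1) * fs / n_window, psd = psd)
}

#' Spectral gait variability: width of the dominant PSD peak
#'
#' Estimates the Welch PSD (window of `window_strides` stride periods,
#' 50% overlap, mean-detrended), locates the dominant peak in the
#' 0.5-4 Hz gait band, and returns its full width at half maximum via
#' linear interpolation. A broader peak means less consistent cycle
#' timing. If a half-maximum crossing lies outside the band, the width is
#' truncated at the band edge and flagged with attribute
#' `truncated = TRUE`.
#'
#' @inheritParams harmonic_amplitudes
#' @param window_strides Welch window length in stride periods (default 4).
#' @param band Frequency band searched for the dominant peak, Hz.
#' @param dominance Minimum ratio of peak PSD to the band median for the
#'   peak to count as dominant (default 5).
#' @return FWHM in Hz (attribute `peak_frequency` gives the peak
#'   location; `truncated` flags band-edge truncation).
#' @export
gait_variability <- function(x, fs, stride_frequency, window_strides = 4,
                             band = c(0.5, 4), dominance = 5) {
  assert_that(stride_frequency > 0, "stride_frequency must be > 0")
  n_window <- round(window_strides * fs / stride_frequency)
  assert_that(length(x) >= 2 * n_window,
              "need at least %d samples (2 Welch windows)", 2 * n_window)
  sp <- welch_psd(x, fs, n_window)
  sel <- which(sp$freq >= band[1] & sp$freq <= band[2])
  assert_that(length(sel) >= 3, "gait band unresolved at this window length")
  pk <- sel[which.max(sp$psd[sel])]
  med <- stats::median(sp$psd[sel])
  if (med <= 0 || sp$psd[pk] < dominance * med) {
    stopf("no dominant spectral peak in the gait band")
  }
  half <- sp$psd[pk] / 2
  cross <- function(dir) {
    i <- pk
    lim <- if (dir < 0) min(sel) else max(sel)
    while (i != lim && sp$psd[i + dir] >= half) i <- i + dir
    if (i == lim) return(structure(sp$freq[lim], truncated = TRUE))
    f1 <- sp$freq[i]; f2 <- sp$freq[i + dir]
    p1 <- sp$psd[i]; p2 <- sp$psd[i + dir]
    structure(f1 + (half - p1) * (f2 - f1) / (p2 - p1), truncated = FALSE)
  }
  left <- cross(-1L)
  right <- cross(+1L)
  structure(as.numeric(right) - as.numeric(left),
            peak_frequency = sp$freq[pk],
            truncated = attr(left, "truncated") || attr(right, "truncated"))
}
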