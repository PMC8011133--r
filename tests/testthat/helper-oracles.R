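# Independent brute-force oracles used across the suite. These must stay
# naive implementations of the definitions, independent of the package's
# computation paths.

# O(n^2) unbiased normalized autocorrelation of the mean-centred signal.
brute_unbiased_autocorr <- function(x, max_lag) {
  x <- x - mean(x)
  v <- sum(x^2) / length(x)
  vapply(0:max_lag, function(tau) {
    n <- length(x)
    s <- sum(x[seq_len(n - tau)] * x[seq_len(n - tau) + tau]) / (n - tau)
    s / v
  }, numeric(1))
}

# AUC by explicit pair counting, ties worth one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Amplitudes at k * f0 by least-squares fit of sin/cos pairs.
ls_harmonic_amplitudes <- function(x, fs, f0, n_harmonics) {
  t <- (seq_along(x) - 1) / fs
  cols <- list()
  for (k in seq_len(n_harmonics)) {
    cols[[paste0("c", k)]] <- cos(2 * pi * k * f0 * t)
    cols[[paste0("s", k)]] <- sin(2 * pi * k * f0 * t)
  }
  X <- do.call(cbind, cols)
  beta <- stats::coef(stats::lm(x ~ X))[-1]
  vapply(seq_len(n_harmonics), function(k) {
    sqrt(beta[[paste0("Xc", k)]]^2 + beta[[paste0("Xs", k)]]^2)
  }, numeric(1))
}

# Wrap a bare signal matrix into a preprocessed-looking trial for event
# detection tests.
make_clean_trial <- function(vt, fs = 148, timed_duration = NULL,
                             ml = NULL, ap = NULL,
                             sensor_site = "lower_trunk") {
  n <- length(vt)
  tr <- new_raw_trial(
    "test", sensor_site, fs,
    data.frame(time_s = (seq_len(n) - 1) / fs,
               acc_ml_g = ml %||% numeric(n),
               acc_ap_g = ap %||% numeric(n),
               acc_vt_g = vt),
    timed_duration %||% (n / fs))
  tr$gravity_removed <- TRUE
  tr$filtered <- TRUE
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small, fast preprocessed simulated trunk trial plus its events.
sim_clean_trunk <- function(..., seed = 1L) {
  cfg <- gait_sim_config(..., seed = seed)
  preprocess_trial(simulate_trial(cfg, "lower_trunk"))
}

# Deterministic gaussian matrix without touching the ambient RNG stream.
with_seed_matrix <- function(seed, n, p) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}
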