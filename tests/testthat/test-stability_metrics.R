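test_that("RMS follows its closed forms", {
  fs <- 100; t <- (0:(10 * fs - 1)) / fs
  expect_equal(acc_rms(0.2 * sin(2 * pi * 2 * t)), 0.2 / sqrt(2),
               tolerance = 1e-6)
  expect_equal(acc_rms(c(0.1, -0.2, 0.3, 0.0)), sqrt(0.14 / 4),
               tolerance = 1e-12)
  expect_identical(acc_rms(numeric(5)), 0)
  expect_error(acc_rms(numeric(0)), "empty")
  # zero-mean RMS equals the population SD
  set.seed(1); x <- rnorm(500); x <- x - mean(x)
  expect_equal(acc_rms(x), sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
})

test_that("unbiased autocorrelation matches the O(n^2) oracle exactly", {
  set.seed(42)
  for (n in c(8, 17, 33, 64)) {
    x <- rnorm(n)
    got <- unbiased_autocorr(x, n - 1)
    expect_equal(got, brute_unbiased_autocorr(x, n - 1), tolerance = 1e-12)
  }
})

test_that("regularity of the printed alternating series is exactly 1", {
  x <- c(1, -1, 1, -1, 1, -1, 1, -1)
  reg <- autocorr_regularity(x, fs = 1, stride_frequency = 0.25)
  oracle <- brute_unbiased_autocorr(x, 5)
  expect_equal(reg$sr1, min(1, oracle[3]), tolerance = 1e-12)  # lag 2
  expect_equal(reg$sr2, min(1, max(oracle[4:6])), tolerance = 1e-12)
  expect_equal(reg$sr1, 1)
  expect_equal(reg$sr2, 1)
})

test_that("stride-frequency estimation agrees between events and autocorrelation", {
  tr <- sim_clean_trunk(stride_time_mean = 1.1, asymmetry = 0.2,
                        duration = 22, seed = 5L)
  ev <- detect_steps(tr)
  f_ev <- estimate_stride_frequency(events = ev)
  f_ac <- estimate_stride_frequency(tr$acc$acc_vt_g, 148)
  expect_equal(f_ev, 1 / 1.1, tolerance = 0.02)
  expect_lt(abs(f_ac - f_ev) / f_ev, 0.05)
  ev0 <- ev; ev0$stride_durations <- rep(1.0, 10)
  expect_identical(estimate_stride_frequency(events = ev0), 1.0)
  set.seed(3)
  expect_error(estimate_stride_frequency(rnorm(3000), 148), "no periodicity")
})

test_that("harmonic amplitudes match a least-squares sinusoid fit", {
  f0 <- 1 / 1.05
  tr <- simulate_trial(gait_sim_config(stride_time_mean = 1.05,
                                       stride_time_jitter_sd = 0,
                                       asymmetry = 0.2, noise_sd = 0,
                                       duration = 21, seed = 6L))
  x <- tr$acc$acc_vt_g - mean(tr$acc$acc_vt_g)
  n <- round(floor(length(x) / (148 / f0)) * 148 / f0)
  x <- x[seq_len(n)]
  got <- harmonic_amplitudes(x, 148, f0, 8)
  want <- ls_harmonic_amplitudes(x, 148, f0, 8)
  keep <- want > 1e-4      # relative comparison on non-null harmonics
  expect_true(all(abs(got[keep] - want[keep]) / want[keep] < 0.01))
})

test_that("harmonic ratio respects construction and axis conventions", {
  fs <- 148; f0 <- 1; t <- (0:(20 * fs - 1)) / fs
  x <- 1.2 * cos(2 * pi * 2 * t) + 0.8 * sin(2 * pi * 4 * t) +  # even: 2.0
    0.6 * cos(2 * pi * 1 * t) + 0.4 * sin(2 * pi * 3 * t)       # odd: 1.0
  expect_equal(as.numeric(harmonic_ratio(x, fs, f0, axis = "vt")), 2.0,
               tolerance = 1e-6)
  # ML is inverted by convention...
  expect_equal(as.numeric(harmonic_ratio(x, fs, f0, axis = "ml")), 0.5,
               tolerance = 1e-6)
  expect_identical(attr(harmonic_ratio(x, fs, f0, axis = "ml"),
                        "orientation"), "odd/even")
  # ...unless the uniform even/odd reading is requested
  expect_equal(as.numeric(harmonic_ratio(x, fs, f0, axis = "ml",
                                         hr_ml_inverted = FALSE)), 2.0,
               tolerance = 1e-6)

  # pure stride-frequency sinusoid: ML denominator (even sum) vanishes
  pure <- cos(2 * pi * f0 * t)
  deg <- harmonic_ratio(pure, fs, f0, axis = "ml")
  expect_true(is.infinite(deg) && isTRUE(attr(deg, "degenerate")))
  expect_error(harmonic_ratio(numeric(length(t)) + 1e-15, fs, f0,
                              axis = "vt"),
               "degenerate harmonic content")
})

test_that("alternate-step scaling lowers step but not stride regularity", {
  tr <- sim_clean_trunk(stride_time_jitter_sd = 0, asymmetry = 0.5,
                        noise_sd = 0, seed = 2L)
  f0 <- 1.0
  reg <- autocorr_regularity(tr$acc$acc_vt_g, 148, f0)
  expect_gte(reg$sr2, 0.99)
  expect_lt(reg$sr1, reg$sr2)
})

test_that("gait symmetry is the order-invariant min/max ratio", {
  expect_equal(as.numeric(gait_symmetry(0.8, 0.8)), 1.0)
  expect_equal(as.numeric(gait_symmetry(0.6, 0.9)), 2 / 3, tolerance = 1e-12)
  expect_equal(as.numeric(gait_symmetry(0.9, 0.6)), 2 / 3, tolerance = 1e-12)
  expect_equal(as.numeric(gait_symmetry(-0.5, 0.5)), 1.0)
  expect_equal(attr(gait_symmetry(0.6, 0.9), "raw_ratio"), 2 / 3,
               tolerance = 1e-12)
  expect_error(gait_symmetry(0, 0), "zero")
})

test_that("Welch PSD satisfies Parseval within 1%", {
  fs <- 128; n <- 4096; t <- (0:(n - 1)) / fs
  # bin-aligned tones so the windowed power bookkeeping is exact up to O(1/n)
  x <- 0.5 * sin(2 * pi * 2 * t) + 0.3 * sin(2 * pi * 5 * t)
  sp <- welch_psd(x, fs = fs, n_window = n)  # single full window
  df <- sp$freq[2] - sp$freq[1]
  expect_equal(sum(sp$psd) * df, 0.5^2 / 2 + 0.3^2 / 2, tolerance = 0.01)
})

test_that("spectral peak width reflects timing jitter", {
  width0 <- {
    tr <- sim_clean_trunk(stride_time_jitter_sd = 0, noise_sd = 0,
                          duration = 30, seed = 3L)
    gait_variability(tr$acc$acc_vt_g, 148, 1.0)
  }
  # jitter-free: line spectrum, width bounded by the window resolution
  res <- 148 / round(4 * 148 / 1.0)
  expect_lte(as.numeric(width0), 2 * res)

  widths <- vapply(c(0.01, 0.05), function(j) {
    mean(vapply(1:8, function(s) {
      tr <- sim_clean_trunk(stride_time_jitter_sd = j, duration = 30,
                            seed = 100L + s)
      as.numeric(gait_variability(tr$acc$acc_vt_g, 148, 1.0))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(widths[1], widths[2])

  set.seed(5)
  expect_error(gait_variability(rnorm(6000), 148, 1.0), "no dominant")
})

test_that("compute_all returns 41 well-formed features and flags failures", {
  pair <- simulate_trial_pair(gait_sim_config(seed = 10L))
  trunk <- preprocess_trial(pair$lower_trunk)
  head <- preprocess_trial(pair$head)
  ev <- detect_steps(trunk)
  f <- compute_all(head, trunk, ev)
  expect_identical(names(f), gait_feature_names())
  expect_length(f, 41)
  expect_true(all(is.finite(f)))
  for (site in c("trunk", "head")) {
    for (ax in c("vt", "ml", "ap")) {
      expect_true(f[paste0(site, "_", ax, "_sr1")] >= -1 &&
                    f[paste0(site, "_", ax, "_sr1")] <= 1)
      expect_true(f[paste0(site, "_", ax, "_symmetry")] >= 0 &&
                    f[paste0(site, "_", ax, "_symmetry")] <= 1)
    }
  }
  # determinism
  expect_identical(f, compute_all(head, trunk, ev))

  # constant head signal: head metrics flagged missing, trunk intact
  head_dead <- head
  for (col in c("acc_ml_g", "acc_ap_g", "acc_vt_g")) {
    head_dead$acc[[col]] <- numeric(nrow(head_dead$acc))
  }
  f2 <- compute_all(head_dead, trunk, ev)
  # constant signal: RMS is legitimately 0, everything else is undefined
  expect_equal(unname(f2[grep("^head_.*_rms$", names(f2))]), rep(0, 3))
  other <- grep("^head_", names(f2), value = TRUE)
  other <- other[!grepl("_rms$", other)]
  expect_true(all(is.na(f2[other])))
  expect_true(all(is.finite(f2[grep("^trunk_", names(f2))])))
  expect_true(length(attr(f2, "flags")) >= 15)
})
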