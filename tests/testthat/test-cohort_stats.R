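test_that("normality screening classifies and transforms as specified", {
  set.seed(11)
  norm <- normality_screen(rnorm(200))
  expect_identical(norm$classification, "normal")
  expect_identical(norm$transform, "none")

  set.seed(12)
  ln <- normality_screen(rlnorm(200))
  expect_identical(ln$classification, "skewed")
  expect_identical(ln$transform, "log10")
  # the transformed sample is normal again
  expect_gt(nortest::lillie.test(ln$values)$p.value, 0.05)

  set.seed(13)
  with_zero <- c(0, rlnorm(199))
  scr <- normality_screen(with_zero)
  expect_identical(scr$transform, "none")
  expect_identical(scr$flag, "nonpositive")

  deg <- normality_screen(rep(3, 10))
  expect_identical(deg$classification, "degenerate")
  expect_error(normality_screen(1:3), "at least 5")
})

test_that("speed adjustment removes the speed effect and is idempotent", {
  set.seed(21)
  speeds <- runif(100, 0.9, 1.4)

  # perfectly speed-determined feature collapses to the grand mean
  v <- 2 * speeds
  adj <- speed_adjust(v, speeds)
  expect_equal(adj, rep(mean(v), 100), tolerance = 1e-10)

  # residual orthogonality and idempotence
  y <- speeds + rnorm(100, 0, 0.2)
  a1 <- speed_adjust(y, speeds)
  expect_lt(abs(cor(a1, speeds)), 1e-10)
  expect_equal(speed_adjust(a1, speeds), a1, tolerance = 1e-10)

  # a speed-independent feature is barely changed
  z <- rnorm(100)
  az <- speed_adjust(z, speeds)
  slope_se <- summary(lm(z ~ speeds))$coefficients[2, 2]
  expect_lt(mean(abs(az - z)), 2 * slope_se * sd(speeds))

  expect_warning(speed_adjust(y, rep(1, 100)), "zero variance")
})

test_that("one-way ANOVA matches hand computation and R's oneway.test", {
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)

  # SS_between = 6, SS_within = 6, df = (2, 6) -> F = 3, p ~ 0.125
  an <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(an$f, 3.0, tolerance = 1e-12)
  expect_equal(an$p, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(an$p, 0.125, tolerance = 1e-3)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(31)
  g1 <- rnorm(12); g2 <- rnorm(15, 0.5)
  t2 <- t.test(g1, g2, var.equal = TRUE)$statistic^2
  expect_equal(one_way_anova(list(g1, g2))$f, unname(t2), tolerance = 1e-10)

  # cross-check against stats::oneway.test
  g3 <- rnorm(10, 1)
  ot <- oneway.test(v ~ g, data.frame(v = c(g1, g2, g3),
                                      g = rep(letters[1:3], c(12, 15, 10))),
                    var.equal = TRUE)
  an2 <- one_way_anova(list(g1, g2, g3))
  expect_equal(an2$f, unname(ot$statistic), tolerance = 1e-10)
  expect_equal(an2$p, ot$p.value, tolerance = 1e-10)

  # invariance under shift, F unchanged under scaling
  sh <- one_way_anova(list(g1 + 7, g2 + 7, g3 + 7))
  sc <- one_way_anova(list(g1 * 3, g2 * 3, g3 * 3))
  expect_equal(sh$f, an2$f, tolerance = 1e-10)
  expect_equal(sc$f, an2$f, tolerance = 1e-10)
})

test_that("DHI staging maps the printed boundaries exactly", {
  expect_identical(assign_dhi_subgroup(30), "mild")
  expect_identical(assign_dhi_subgroup(31), "moderate")
  expect_identical(assign_dhi_subgroup(60), "moderate")
  expect_identical(assign_dhi_subgroup(61), "severe")
  expect_identical(assign_dhi_subgroup(c(0, 100)), c("mild", "severe"))
  expect_error(assign_dhi_subgroup(101), "0, 100")
  expect_error(assign_dhi_subgroup(-1), "0, 100")
})

test_that("cohort statistics run on a small simulated feature table", {
  set.seed(41)
  n <- 30
  feats <- data.frame(
    subject_id = sprintf("S%02d", 1:n),
    group = rep(c("healthy", "mild", "moderate", "severe"), c(12, 8, 6, 4)),
    cohort = rep(c("healthy", "bppv"), c(12, 18)),
    dhi = c(rep(0, 12), round(runif(8, 0, 30)), round(runif(6, 31, 60)),
            round(runif(4, 61, 100))))
  feats[setdiff(gait_feature_names(), names(feats))] <- NA_real_
  feats$walking_speed <- rnorm(n, 1.15, 0.1)
  feats$cadence <- rnorm(n, 115, 8)
  feats$trunk_vt_rms <- 0.15 * feats$walking_speed + rnorm(n, 0, 0.01)
  feats$trunk_vt_hr <- rnorm(n, 3, 0.5) - 0.8 * (feats$cohort == "bppv")

  out <- cohort_group_stats(feats, "cohort",
                            feature_names = c("walking_speed", "cadence",
                                              "trunk_vt_rms", "trunk_vt_hr"))
  expect_identical(out$feature,
                   c("walking_speed", "cadence", "trunk_vt_rms",
                     "trunk_vt_hr"))
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_true(all(out$f >= 0))
  # stability metrics are speed-adjusted, temporospatial ones are not
  expect_identical(out$speed_adjusted, c(FALSE, FALSE, TRUE, TRUE))
  # the injected group effect on HR is detected
  expect_lt(out$p[out$feature == "trunk_vt_hr"], 0.05)

  dhi_out <- cohort_group_stats(feats, "dhi",
                                feature_names = c("trunk_vt_hr"))
  expect_true(all(c("mean_mild", "mean_moderate", "mean_severe") %in%
                    names(dhi_out)))
})
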