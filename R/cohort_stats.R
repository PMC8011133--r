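# Cohort statistics: normality screening with log10 transform, walking-
# speed adjustment, one-way ANOVA, and DHI severity staging.

#' Screen a feature for normality and transform if skewed
#'
#' Tests the values against a normal distribution with a
#' Kolmogorov-Smirnov test. By default the Lilliefors variant is used
#' (mean and SD estimated from the sample, as common statistics packages
#' do); `exact_params = TRUE` runs the plain one-sample KS test against
#' `N(mean(x), sd(x))` instead. Features that fail at `alpha` and are
#' positively skewed are log10-transformed; if such a feature contains
#' non-positive values the transform is skipped and flagged.
#'
#' @param x Numeric vector (at least 5 values).
#' @param alpha Significance level for the normality test (default 0.05).
#' @param exact_params Use the plain KS test instead of Lilliefors.
#' @return List: `classification` (`"normal"`/`"skewed"`/`"degenerate"`),
#'   `p_value`, `skewness`, `transform` (`"none"`/`"log10"`), `flag`
#'   (e.g. `"nonpositive"`), `values` (transformed when applicable).
#' @export
normality_screen <- function(x, alpha = 0.05, exact_params = FALSE) {
  assert_that(length(x) >= 5, "need at least 5 values")
  assert_that(all(is.finite(x)), "values must be finite")
  if (sd_or_zero(x) < 1e-300) {
    return(list(classification = "degenerate", p_value = NA_real_,
                skewness = NA_real_, transform = "none",
                flag = "degenerate", values = x))
  }
  p <- if (exact_params) {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))$p.value
  } else {
    nortest::lillie.test(x)$p.value
  }
  skew <- e1071::skewness(x, type = 2)
  if (p >= alpha || skew <= 0) {
    cls <- if (p >= alpha) "normal" else "skewed"
    return(list(classification = cls, p_value = p, skewness = skew,
                transform = "none", flag = NULL, values = x))
  }
  if (any(x <= 0)) {
    return(list(classification = "skewed", p_value = p, skewness = skew,
                transform = "none", flag = "nonpositive", values = x))
  }
  list(classification = "skewed", p_value = p, skewness = skew,
       transform = "log10", flag = NULL, values = log10(x))
}

#' Adjust a gait variable for walking speed
#'
#' Removes the linear influence of gait speed by ordinary least squares
#' of the feature on walking speed over all subjects pooled: the adjusted
#' value is the regression residual plus the grand mean, so adjusted
#' values are exactly uncorrelated with speed and keep the original
#' scale. Idempotent. With `per_group`, the regression (and grand mean)
#' is fit within each group separately.
#'
#' @param values Numeric feature values.
#' @param speeds Walking speeds (m/s), same length.
#' @param group Optional group factor for `per_group = TRUE`.
#' @param per_group Fit the adjustment within groups (default FALSE).
#' @return Adjusted values.
#' @export
speed_adjust <- function(values, speeds, group = NULL, per_group = FALSE) {
  assert_that(length(values) == length(speeds) && length(values) >= 3,
              "values and speeds must have equal length >= 3")
  if (per_group && !is.null(group)) {
    out <- values
    for (g in unique(group)) {
      sel <- group == g
      out[sel] <- speed_adjust(values[sel], speeds[sel])
    }
    return(out)
  }
  if (sd_or_zero(speeds) < 1e-300) {
    warning("zero variance in walking speed; returning values unadjusted",
            call. = FALSE)
    return(values)
  }
  fit <- stats::lm(values ~ speeds)
  as.numeric(stats::residuals(fit)) + mean(values)
}

#' Classic one-way fixed-effects ANOVA
#'
#' F = MS_between / MS_within with (k - 1, N - k) degrees of freedom;
#' p from the F distribution. When every group is identical (zero
#' between- and within-group variance) the test is degenerate and
#' reported as F = 0, p = 1.
#'
#' @param groups A list of two or more numeric vectors, each with at
#'   least 2 values.
#' @return List: `f`, `p`, `df` (length 2), `group_means`, `group_sds`.
#' @export
one_way_anova <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2,
              "need at least 2 groups")
  assert_that(all(vapply(groups, length, integer(1)) >= 2),
              "each group needs at least 2 values")
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  n_tot <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  grand <- sum(ns * means) / n_tot
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- c(k - 1, n_tot - k)
  if (ss_w < 1e-300) {
    if (ss_b < 1e-300) {
      return(list(f = 0, p = 1, df = df, group_means = means,
                  group_sds = sds))
    }
    return(list(f = Inf, p = 0, df = df, group_means = means,
                group_sds = sds))
  }
  f <- (ss_b / df[1]) / (ss_w / df[2])
  list(f = f, p = stats::pf(f, df[1], df[2], lower.tail = FALSE),
       df = df, group_means = means, group_sds = sds)
}

#' Stage a DHI score into a severity subgroup
#'
#' Dizziness Handicap Inventory staging: 0-30 mild, 31-60 moderate,
#' 61-100 severe.
#'
#' @param dhi Integer DHI score(s) in 0-100.
#' @return Character vector: `"mild"`, `"moderate"` or `"severe"`.
#' @export
assign_dhi_subgroup <- function(dhi) {
  assert_that(all(is.finite(dhi)) && all(dhi >= 0 & dhi <= 100),
              "DHI scores must lie in [0, 100]")
  cut(dhi, breaks = c(-0.5, 30.5, 60.5, 100.5),
      labels = c("mild", "moderate", "severe")) |> as.character()
}

#' Per-feature group comparison across a cohort
#'
#' Reproduces the statistical pipeline on a feature table: each feature
#' is screened for normality (log10-transforming positively skewed
#' features), the walking-stability features are adjusted for walking
#' speed, and group differences are tested with one-way ANOVA. Two
#' groupings are supported: healthy vs BPPV, and the three DHI severity
#' subgroups within patients. P values are reported per feature without
#' multiple-testing correction, as is conventional in this literature; a
#' Benjamini-Hochberg column can be added with `adjust_p`.
#'
#' @param features Feature table from [cohort_features()].
#' @param grouping `"cohort"` (healthy vs BPPV) or `"dhi"` (mild /
#'   moderate / severe within patients).
#' @param feature_names Features to test; defaults to the stability and
#'   temporospatial variables (excluding walking speed itself and the raw
#'   step count).
#' @param alpha Normality-test level.
#' @param speed_adjust_stability Adjust stability features for walking
#'   speed (default TRUE).
#' @param adjust_p Add Benjamini-Hochberg adjusted p values (default
#'   FALSE).
#' @return Data frame: feature, per-group mean and SD, F, p, transform,
#'   speed-adjustment flag.
#' @export
cohort_group_stats <- function(features, grouping = c("cohort", "dhi"),
                               feature_names = NULL, alpha = 0.05,
                               speed_adjust_stability = TRUE,
                               adjust_p = FALSE) {
  grouping <- match.arg(grouping)
  if (grouping == "dhi") {
    features <- features[features$cohort == "bppv", ]
    features$stat_group <- assign_dhi_subgroup(features$dhi)
    levels_ <- c("mild", "moderate", "severe")
  } else {
    features$stat_group <- features$cohort
    levels_ <- c("healthy", "bppv")
  }
  assert_that(all(levels_ %in% features$stat_group),
              "grouping '%s': some groups are empty", grouping)

  temporospatial_names <- c("walking_speed", "step_length", "cadence",
                            "step_timing_variability")
  feature_names <- feature_names %||%
    setdiff(gait_feature_names(), "n_steps")

  rows <- lapply(feature_names, function(fn) {
    vals <- features[[fn]]
    ok <- is.finite(vals)
    vals <- vals[ok]
    grp <- features$stat_group[ok]
    spd <- features$walking_speed[ok]
    if (length(vals) < 5 || any(table(grp) < 2)) return(NULL)

    scr <- normality_screen(vals, alpha = alpha)
    v <- scr$values
    adjusted <- FALSE
    if (speed_adjust_stability && !(fn %in% temporospatial_names)) {
      v <- speed_adjust(v, spd)
      adjusted <- TRUE
    }
    an <- one_way_anova(split(v, factor(grp, levels = levels_)))
    stats_row <- data.frame(feature = fn, f = an$f, p = an$p,
                            transform = scr$transform,
                            speed_adjusted = adjusted,
                            stringsAsFactors = FALSE)
    for (g in levels_) {
      stats_row[[paste0("mean_", g)]] <- mean(vals[grp == g])
      stats_row[[paste0("sd_", g)]] <- sd_or_zero(vals[grp == g])
    }
    stats_row
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (adjust_p && nrow(out)) out$p_bh <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
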