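# vestigait

Walking-stability analysis from body-worn accelerometers, aimed at
objective staging of dizziness handicap in benign paroxysmal positional
vertigo (BPPV).

Two tri-axial accelerometers — back of the head and the L3 lower trunk —
record level walking at 148 Hz along the mediolateral (ML), anteroposterior
(AP) and vertical (VT) axes while the middle 10 m of the walk is timed.
`vestigait` turns those signals into:

* **Temporospatial variables** — walking speed, step length, cadence,
  step-timing variability (SD of gait-cycle durations), step count.
* **Walking-stability metrics**, per axis and sensor:
  * RMS of the gravity-free acceleration;
  * harmonic ratio, HR = Σ even / Σ odd stride-harmonic amplitudes on
    VT/AP (inverted on ML), evaluated at exact multiples of the stride
    frequency — higher means smoother, more symmetric gait;
  * step and stride regularity SR1/SR2, the unbiased autocorrelation
    coefficients at the step and stride lags;
  * gait symmetry, min(|SR1|, |SR2|) / max(|SR1|, |SR2|);
  * gait variability, the full width at half maximum of the dominant
    peak of the Welch power spectrum.
* **Cohort statistics** — Kolmogorov–Smirnov (Lilliefors) normality
  screening with log10 transform of skewed features, walking-speed
  adjustment by pooled OLS residuals, one-way ANOVA across
  healthy/BPPV and across DHI severity subgroups (mild 0–30,
  moderate 31–60, severe 61–100).
* **Severity model** — z-scored features reduced to 4 principal
  components feeding a one-vs-rest linear SVM, evaluated with repeated
  stratified 5-fold cross-validation and per-class ROC/AUC, with all
  preprocessing fit inside the training folds.

Because no raw clinical recordings are available, the package ships a
first-class synthetic gait simulator (stride-harmonic signal structure,
step-level timing jitter, alternating-step asymmetry, sensor noise,
+1 g gravity offset) that generates single trials and whole
severity-graded cohorts; every stage of the pipeline is developed and
tested against it.

## Worked example

```r
library(vestigait)

cfg <- gait_sim_config(stride_time_mean = 1.05, asymmetry = 0.2, seed = 1)
pair <- simulate_trial_pair(cfg, subject_id = "demo")
trunk <- preprocess_trial(pair$lower_trunk)   # gravity off, 22 Hz low-pass
head  <- preprocess_trial(pair$head)
events <- detect_steps(trunk)                 # VT lower-trunk peaks
feats <- compute_all(head, trunk, events)     # 41 named features
round(feats[c("walking_speed", "cadence", "step_timing_variability",
              "trunk_vt_rms", "trunk_vt_hr", "trunk_vt_sr1",
              "trunk_vt_sr2", "trunk_vt_symmetry")], 3)
#>           walking_speed                 cadence step_timing_variability
#>                   1.193                 117.000                   0.015
#>            trunk_vt_rms             trunk_vt_hr            trunk_vt_sr1
#>                   0.197                   4.321                   0.912
#>            trunk_vt_sr2       trunk_vt_symmetry
#>                   0.976                   0.934
```

The walk covers 10 m at 1.19 m/s with 117 steps/min; trunk VT
acceleration has RMS 0.20 g; the injected 20% step asymmetry shows up as
a finite harmonic ratio (4.3), a step regularity (0.91) below the stride
regularity (0.98), and a symmetry of 0.93.

The one-command demo reproduces the full synthetic study — 27 healthy
controls plus 12 mild, 9 moderate and 6 severe subjects, 6 trials each,
both sensors — end to end:

```r
res <- run_demo(out_dir = "demo_out", seed = 42)
res$cv
#> <cv_report> 5-fold CV x 10 repeats, PCA k = 4, linear SVM C = 1
#>   healthy    AUC 0.999 +/- 0.006 (50 fold evaluations)
#>   mild       AUC 0.751 +/- 0.183 (50 fold evaluations)
#>   moderate   AUC 0.826 +/- 0.109 (50 fold evaluations)
#>   severe     AUC 1.000 +/- 0.000 (50 fold evaluations)
```

Per-class AUCs order with the severity gradient built into the
generator; the small mild/moderate groups (12 and 9 subjects) make
their fold AUCs noisy, exactly as expected at this cohort size. The
output directory contains `features.csv`, `stats_cohort.csv`,
`stats_dhi.csv`, `cv_roc_points.csv`, `cv_summary.json` and a run log;
every file embeds the config hash and seed, and re-running the same
config reproduces them byte for byte.

A thin command-line front end with `simulate`, `extract`, `stats`,
`classify`, `run` and `demo` subcommands lives in
`inst/cli/vestigait.R`; pipelines can also be driven from a YAML config
via `read_pipeline_config()`.

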