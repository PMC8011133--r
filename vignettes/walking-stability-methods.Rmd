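---
title: "Walking-stability analysis from head and lower-trunk accelerometry"
author: "vestigait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking-stability analysis from head and lower-trunk accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestigait)
```

## The problem

Benign paroxysmal positional vertigo (BPPV) degrades balance control
during walking: patients adopt a conservative gait (slower, shorter
steps) yet remain at elevated fall risk because the quality of their
gait — its smoothness, regularity and left/right symmetry — is impaired.
Dizziness handicap is conventionally staged with the self-reported
Dizziness Handicap Inventory (DHI, 0–100: mild 0–30, moderate 31–60,
severe 61–100), which lacks an objective counterpart.

`vestigait` implements an instrumented version of that assessment: two
tri-axial accelerometers (back of the head; third lumbar vertebra,
"lower trunk") record level walking at 148 Hz along the mediolateral
(ML = X), anteroposterior (AP = Y) and vertical (VT = Z) axes while the
middle 10 m of a 20 m walkway is timed. From these signals the package
computes five temporospatial variables and six walking-stability metrics
per axis and sensor, compares groups statistically, and stages severity
with a PCA + linear-SVM classifier.

## Signal model and the synthetic cohort

No raw recordings accompany the study design this package implements, so
a first-class simulator stands in for the instrument and defines the
conditions under which the package is tested.

A walking trial is modelled as a sum of stride-frequency harmonics whose
phase advances through *jittered step durations*:

* VT and AP axes carry **even** stride harmonics only (the step
  frequency is twice the stride frequency, and both feet produce the
  same vertical/forward acceleration pattern in symmetric gait);
* the ML axis carries predominantly **odd** harmonics (lateral sway
  reverses direction once per stride);
* left/right **asymmetry** `a` multiplies alternate steps of the VT/AP
  signal by `1 + a` and `1 − a`, which moves a proportional share of
  even-harmonic power into the odd harmonics — precisely the quantity
  harmonic-ratio and symmetry metrics are designed to detect;
* **timing jitter** is injected per step (half cycle), with the step SD
  scaled by $1/\sqrt{2}$ so that the cycle-to-cycle stride-duration SD
  equals the configured `stride_time_jitter_sd`. Jittering whole strides
  instead would leave the two halves of every cycle perfectly aligned:
  step regularity would stay at 1 under any timing noise while stride
  regularity absorbed all of it, which is neither realistic nor neutral
  for the symmetry metric (see *Numerical choices*);
* the VT axis carries the +1 g offset of a statically calibrated upright
  sensor, and white noise (`noise_sd`, default 0.02 g) is added per
  axis and sensor.

Because the phase truly accumulates jittered durations, the width of the
dominant spectral peak grows with jitter, which is what the
gait-variability metric measures.

The cohort generator reproduces the study shape — 27 healthy controls
plus 12 mild, 9 moderate and 6 severe BPPV subjects, 6 trials per
subject, both sensors — with severity-graded parameter profiles
(speed 1.20 → 1.05 m/s, stride time 1.00 → 1.12 s, stride-timing jitter
0.012 → 0.032 s, asymmetry 0.05 → 0.26 from healthy to severe),
subject-level random offsets around the group profile, and DHI scores
drawn uniformly within each group's range (healthy subjects score 0).
The group profiles are *illustrative*: they grade monotonically with
severity and produce plausible magnitudes, but no raw cohort exists to
calibrate them against, so simulated group means must not be read as
reproductions of any published table. Default amplitude profiles give a
lower-trunk VT RMS near 0.2 g; the head attenuates VT/AP by 0.8 and
amplifies ML by 1.1.

What the simulator deliberately omits: sensor orientation drift,
gyroscope channels, turning segments, start/stop transients,
non-stationary pacing, and any biomechanically validated forward
dynamics. Passing tests therefore demonstrate that the *estimators
recover injected signal structure*, not that the package has been
validated on patients.

## Preprocessing

Gravity is removed by per-axis mean subtraction over the analysed
segment — the minimal interpretation consistent with static ±1 g
calibration; attitude estimation is out of scope. Signals are then
low-pass filtered with a second-order Butterworth at 22 Hz, applied
forward–backward (zero phase), so peak timing is preserved at the cost
of squaring the magnitude response. The filter operates around the
per-axis mean and re-centres its output, making DC gain exactly 1;
filtering and gravity removal therefore commute to machine precision.

A subject's trial set is rejected when the coefficient of variation
(population SD / mean) of the timed 10 m durations exceeds 5%; an
absolute SD threshold would be dimensionally meaningless.

## Events and temporospatial variables

Steps are the peaks of the vertical lower-trunk acceleration. The step
period is first estimated from the dominant VT spectral frequency in
0.5–4 Hz (an error is raised when no frequency dominates — "no gait
detected"); local maxima are kept when their prominence and height both
exceed 0.3 × SD(VT), then thinned to a minimum separation of half a step
period. The height criterion matters at realistic noise levels: valley
noise blips can have sufficient *prominence*, but genuine step peaks of
the gravity-free VT axis are positive. All three thresholds are
artifact decisions and configurable.

From the events: walking speed = 10 m / timed duration; step length =
distance / steps; cadence = steps per minute; step-timing variability =
sample SD of gait-cycle durations. "Gait cycle" is taken as the stride
(alternate-peak interval) by default, with the successive-step reading
available via `cycle = "step"`. In `compute_all()`, cadence and timing
variability use the whole recorded trial (the definition of cadence is
peaks over the *trial* duration) while step length and the step count
come from events clipped to a central window of the timed duration;
note that counting steps in a fixed window carries an irreducible ±1
boundary-step quantization.

## Stability metrics

All six are computed per axis and sensor, on gravity-free filtered
signals, using the stride frequency from the lower-trunk events for both
sensors (they record the same walk).

* **RMS** — `sqrt(mean(x^2))`, the dispersion about zero.
* **Harmonic ratio (HR)** — amplitudes are evaluated by discrete Fourier
  sums at exact multiples of the stride frequency over a
  whole-stride-trimmed segment (leakage would corrupt the even/odd
  separation), 20 harmonics by default. VT/AP: Σeven / Σodd. ML is
  inverted (Σodd / Σeven) by default, following the harmonic-ratio
  literature in which ML's fundamental is the stride frequency; the
  uniform reading is available with `hr_ml_inverted = FALSE`, and the
  orientation used is recorded on the result. A vanishing denominator
  with real numerator yields `Inf` flagged degenerate.
* **Step/stride regularity (SR1/SR2)** — the unbiased autocorrelation
  (divide by `n − lag`, normalized at lag 0), maximized over windows of
  ±25% around the step and stride lags to tolerate cadence drift. The
  unbiased estimator can marginally exceed 1; coefficients are clamped
  to `[−1, 1]`.
* **Gait symmetry** — `min(|SR1|, |SR2|) / max(|SR1|, |SR2|)`, an
  order-invariant reading of "closeness of SR1/SR2 to 1" on absolute
  values; the raw ratio is attached as an attribute.
* **Gait variability** — Welch PSD (window of 4 stride periods, 50%
  overlap, Hann, mean-detrended), dominant peak in 0.5–4 Hz, full width
  at half maximum by linear interpolation. Reported in Hz; published
  dimensionless variants of this quantity use unstated normalizations,
  so no attempt is made to match their scale. Band-edge truncation is
  flagged on the result.

Per-subject features are the mean over the subject's valid trials,
which keeps cross-validation leakage-free at the subject level. A
failing metric (degenerate input, no dominant peak) becomes `NA` with a
flag; it never silently drops the remaining 40 values.

## Group statistics

Per feature: a Kolmogorov–Smirnov normality screen — Lilliefors variant
by default, since the sample's own mean/SD are used, with the
plain-parameter test behind a flag — log10-transforms positively skewed
features (skipped and flagged when non-positive values make log10
undefined); stability features are adjusted for walking speed by pooled
OLS residuals re-centred at the grand mean (exactly orthogonal to speed
and idempotent; a per-group option exists); and groups are compared with
classic one-way fixed-effects ANOVA. Healthy-vs-BPPV and the
three-DHI-subgroup comparison run as separate analyses. P values are
per-feature without multiple-testing correction, matching the field's
reporting convention; Benjamini–Hochberg is available off by default.

## Severity model

Features are median-imputed, z-scored, reduced to 4 principal
components, and classified with a one-vs-rest linear SVM (C = 1) — the
only multi-class scheme consistent with reporting one AUC per group.
Evaluation uses stratified 5-fold cross-validation repeated 10 times
(the repeat count is an assumption; it is seed-controlled and
configurable), with per-fold, per-class ROC curves and AUCs aggregated
as mean ± SD.

Imputation, standardization and PCA are fit **inside the training
folds** and applied to the held-out fold. Fitting them once on the full
data before splitting lets held-out subjects influence the transform;
`paper_literal = TRUE` reproduces that variant for comparison. Both
transforms are label-independent, so on null data neither mode is
expected to inflate AUC — the leak matters when the transform interacts
with real structure — and the test suite accordingly asserts the
fold-wise fitting itself rather than a null-AUC difference.

AUC is the tie-aware rank statistic (probability a positive outscores a
negative, ties counted ½), identical to the trapezoidal area under the
empirical ROC.

## Numerical choices and degenerate inputs

* Sample SD (n − 1) throughout, except RMS (population convention, so
  zero-mean RMS equals the population SD) and the trial-validity CV
  (population SD, consistent with its worked definition).
* Stride-frequency estimation without events uses the largest
  unbiased-autocorrelation peak with the stride period searched in
  0.5–4 s; for a perfectly step-symmetric signal the step and stride
  lags tie and the estimate may halve — the events-based estimate
  resolves this and is what the pipeline uses.
* The gait-symmetry metric is non-monotone in asymmetry near zero
  whenever timing jitter is present: jitter decorrelates the stride lag
  (two step deviations) more than the step lag (one), so SR2 < SR1 at
  zero asymmetry and a small asymmetry first raises the min/max ratio.
  The parameter-recovery experiments therefore sweep asymmetry with
  timing jitter at zero (sensor noise on), isolating the injected
  parameter.
* Degenerate inputs fail loudly and specifically: empty signals,
  constant signals ("no gait detected"), zero-variance regularity,
  vanishing harmonic denominators, ANOVA on identical groups (F = 0,
  p = 1), zero speed variance (identity with warning).

## Problem sizes

The bundled demo runs the full 54-subject study (6 trials × 2 sensors,
20 s of signal per trial at 148 Hz) and completes in well under five
minutes on a single CPU. The test suite uses the same generator at
smaller sizes — 20-seed sweeps for parameter recovery, 8-subject groups
with 2 × 14 s trials for the severity-ordering checks, 10,000 draws for
ANOVA calibration — chosen to exercise every claim at comfortable
margins while keeping a full run fast.

## Known limitations

Simulated cohorts cannot validate clinical sensitivity; group profiles
are illustrative. Gravity removal by mean subtraction assumes a
constant sensor attitude over the analysed segment. The HR ML
orientation and the stride-vs-step reading of timing variability are
field conventions with documented alternatives, not facts recoverable
from first principles. Nonlinear stability measures (Lyapunov
exponents, entropy), turning analysis, and foot-side attribution are
out of scope.
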