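Package: vestigait
Title: Walking-Stability Analysis of Trunk and Head Accelerometry for
    Vestibular Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying walking stability from
    tri-axial accelerometers worn on the head and lower trunk during timed
    10 m level walking, aimed at staging dizziness handicap in benign
    paroxysmal positional vertigo (BPPV). Provides a synthetic gait-signal
    simulator with controllable stride-harmonic structure, left/right
    asymmetry and cycle-timing jitter; preprocessing (gravity removal,
    zero-phase Butterworth low-pass filtering, trial-set validity checks);
    step detection from vertical lower-trunk acceleration and temporospatial
    gait variables; six walking-stability metrics per axis and sensor (RMS,
    harmonic ratio, step and stride regularity, gait symmetry, spectral
    gait variability); cohort statistics (normality screening, log10
    transform, walking-speed adjustment, one-way ANOVA); and a severity
    classifier (PCA to four components feeding a linear support vector
    machine) evaluated with repeated stratified 5-fold cross-validation and
    one-vs-rest ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    nortest,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
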