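Package: tloadback
Title: Adaptive Calibration and Test-Retest Reliability Analysis for the
    TloadDback Dual Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the TloadDback calibration procedure: generation and
    scoring of combined 1-back letter / number-parity stimulus blocks, the
    stepwise staircase that finds the fastest stimulus time duration (STD)
    sustaining 85 percent weighted accuracy, a psychometric simulated-observer
    model with between-session learning, a three-session counterbalanced
    cohort generator with sleep, sleepiness and fatigue covariates, and the
    test-retest reliability battery (tie-corrected Friedman test,
    Durbin-Conover pairwise comparisons, Spearman correlations, Cronbach's
    alpha / ICC(3,k), change-score frequency distributions, repeated-measures
    ANOVA). Includes a command-line interface for simulation, analysis and
    calibration demos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
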