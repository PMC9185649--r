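Package: fatiguegait
Title: Day-to-Day Reliability of Centre-of-Mass IMU Features During
    Fatiguing Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the between-day reliability of features
    derived from a centre-of-mass (trunk) accelerometer during fatiguing
    treadmill runs. Provides a synthetic running-signal generator with
    subject, trial and fatigue-state variance components; attitude
    correction, initial-contact detection and stride segmentation for
    tri-axial acceleration; extraction of 39 per-sample features (basic
    statistics, sample entropy and RMS ratios over the VT/ML/AP axes and
    the resultant); and the statistical layer of a four-trial
    repeated-measures design: fatigue-state by trial ANOVA, ICC(2,k)
    test-retest reliability with interpretation bins, trial-variable
    ANOVAs, paired RPE tests and the maximal-lactate-steady-state rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
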