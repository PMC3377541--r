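Package: postvar
Title: Accuracy and Precision of Posture Exposure Variance Components
    under Block Sampling Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how data-collection strategies affect
    estimates of between-subjects, between-days and within-day variance
    components of occupational posture exposure. Generates synthetic
    minute-level arm-elevation exposure data with a hierarchical
    random-effects structure and realistic within-day autocorrelation
    (a calibrated mixture of two AR(1) processes), converts 1-Hz
    inclinometer interval codes to minute-level exposure variables,
    standardizes working days to a balanced parent data set by block
    resampling, estimates variance components by the balanced nested
    ANOVA / REML moment estimator, enumerates block sampling strategies,
    and quantifies each strategy's accuracy (bias) and precision (90%
    prediction intervals) by a three-level block bootstrap. Includes the
    analytic deflation factor for the sample variance of an
    autocorrelated block, which explains the estimator bias observed at
    large block sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
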