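Package: sahcgrad
Title: Gravitational-Gradient Biomechanics and Physiological Response
    Analysis for Short-Arm Human Centrifugation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward modelling of g-levels, g-gradients and hydrostatic
    blood pressure along the body during short-arm human centrifugation
    with an arbitrary rotation-axis position, together with the analysis
    pipeline used in gravitational-physiology centrifuge trials: artifact
    rejection of multi-channel cardiovascular time series, cubic-spline
    resampling to a uniform 4 Hz grid, baseline-referenced two-minute
    epoch responses, pre-syncope classification from heart-rate and
    blood-pressure traces, and inference via random-intercept linear
    mixed models with likelihood-ratio tests, one-way ANOVA with Tukey
    honestly-significant-difference comparisons, chi-squared tests of
    pre-syncope frequency and Pearson correlations between responses.
    A synthetic cohort and run generator with known ground truth makes
    the whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
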