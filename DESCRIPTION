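Package: gofcutoffs
Title: Tailored Cutoffs for Goodness-of-Fit Indices in Confirmatory Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo machinery for studying the behaviour of goodness-of-fit
    indices (chi-square, chi-square/df, CFI, RMSEA, SRMR) in confirmatory factor
    analysis of ordered-categorical data, and for deriving tailored (dynamic)
    cutoffs that control the Type I error rate. Includes a crossed simulation
    design over estimator (ML, MLR, DWLS, WLSMV), indicator count, response
    options, response distribution, loading magnitude, sample size, factor
    correlation and model misspecification; ordinal data generation with
    moment-matched category thresholds; built-in CFA estimation (maximum
    likelihood with a Satorra-Bentler type robust statistic, and diagonally
    weighted least squares on polychoric correlations with the mean-and-variance
    adjusted statistic); scenario-specific quantile cutoffs, rejection-rate
    accounting, and a regression-formula predictor of cutoffs from data and
    analysis characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
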