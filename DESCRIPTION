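Package: centilefit
Title: Construction of Gestational-Age-Related Growth Centile Charts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing reference and standard centile charts of
    fetal and newborn size as smooth functions of gestational age. Implements
    fractional-polynomial regression of the mean and standard deviation
    (normal-theory centiles with the half-normal absolute-residual SD
    estimator), LMS-type distributional centile models (normal, power
    exponential, Box-Cox Cole-Green, Box-Cox t, Box-Cox power exponential,
    skew exponential power type 3 and skew t type 3 families, with fractional
    polynomial or penalized-spline parameter curves fitted by maximum
    penalized likelihood), and multilevel random-intercept/slope models for
    longitudinal ultrasound data with triplicate measurements. Includes
    model-selection machinery (AIC, BIC, generalized AIC), worm-plot, Q-Q and
    centile-coverage diagnostics, synthetic data generators emulating
    cross-sectional newborn and longitudinal fetal study designs, and chart
    table/model import-export with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
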