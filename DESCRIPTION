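Package: hingepoint
Title: Threshold-Effect Analysis of a Continuous Exposure on a Binary Outcome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying threshold (change-point)
    effects of a continuous exposure on a binary outcome with logistic
    regression. Implements two-piecewise (hinge) logistic models with a
    profile-likelihood grid search for the turning point, a likelihood-ratio
    test against the one-line model, nonparametric bootstrap percentile
    confidence intervals for the turning point, per-standard-deviation effect
    rescaling, penalized-spline smooth dose-response curves, E-value
    sensitivity analysis for unmeasured confounding, tertile-based
    descriptive tables, and missing-indicator covariate handling. Ships a
    synthetic ICU sepsis cohort generator with a hinge-shaped logit risk so
    the full pipeline is testable without access to restricted clinical
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
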