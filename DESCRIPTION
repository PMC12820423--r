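Package: screenineq
Title: Machine-Learning Decomposition of Socioeconomic Inequality in
    Cancer-Screening Uptake
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring and decomposing socioeconomic inequality in
    the uptake of preventive health services from cross-sectional survey
    microdata. Provides a synthetic generator for NFHS/DHS-like survey tables
    with a known inequality structure, survey-weighted fractional ranks and
    concentration indices (covariance and convenient-regression forms, on
    observed outcomes and on classifier-predicted probabilities), class
    balancing by synthetic minority oversampling, a common interface over
    five classifier families with stability analysis, permutation importance
    and interventional Shapley attributions with an exhaustive oracle, and
    two concentration-index decompositions: the feature-importance times
    feature-inequality product rule, and an exactly additive Shapley-rank
    covariance decomposition, with bootstrap uncertainty.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    ranger,
    xgboost,
    e1071,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
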