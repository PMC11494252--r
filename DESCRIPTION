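Package: rehabsev
Title: Residual Stroke Severity Classification from Robotic Rehabilitation Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for classifying residual stroke severity (no, low,
    or high range of motion) from kinematics recorded during in-home
    robotics-assisted therapy sessions. Provides a seeded simulator for
    class-conditional 30 Hz angle/pressure session streams, activity-level
    feature extraction (winsorization, smoothing, hysteresis movement
    counting, derivative-based force summaries), leakage-safe dataset
    assembly (activity filter, stratified train/test split, train-fitted
    z-scoring), feature-redundancy and principal-component diagnostics, four
    classifiers (gradient-boosted trees, extra trees, multinomial logistic
    regression, and a small feed-forward ReLU network) with stratified
    cross-validation, and confusion-matrix based precision/recall/F1
    reporting with model comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    ranger,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
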