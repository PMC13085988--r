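Package: iclbench
Title: Benchmarking In-Context-Learning Risk Predictors on Small Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing chat-based in-context-learning predictors with
    conventional machine learning on small clinical tabular cohorts. Implements
    schema-driven preprocessing (near-duplicate screening, cleaning, encoding,
    standard scaling), inverted cross-validation sampling with small disjoint
    training folds and large overlapping test sets, chat prompt serialization
    under graded context-ablation variants, probability extraction from
    completion log-probabilities, post hoc calibration (Platt, isotonic, beta)
    with Brier scoring, discrimination and decision-curve metrics, and
    overlap-aware bootstrap inference (cluster-resampled confidence intervals
    for fold means and hierarchical prediction intervals for single splits).
    A synthetic cohort generator with a matching logistic oracle makes the full
    pipeline testable offline; real chat backends plug in behind a uniform
    predictor contract.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    ranger,
    xgboost,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    withr
Config/testthat/edition: 3
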