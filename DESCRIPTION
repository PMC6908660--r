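Package: melmv
Title: Multi-View Ensemble Learning with Missing Values for Fall-Severity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts the severity of inpatient falls from multi-view tabular
    clinical data (demographics, diagnosis categories, procedures, bone-density
    measurements). Implements a stacked ensemble in which each view is learned
    by its own base inducers (logistic regression, support-vector machine or
    regression), missing views are handled by substituting the classifier's
    optimal ROC cutoff together with a missing-indicator flag, and a
    wrapper-selected logistic meta-learner combines the stage-one outputs into
    a severity index. Includes baseline comparators (single-view models with
    chained-equation imputation, a random-forest meta-learner, simple
    ensembles), an evaluation harness (rank-based AUC, DeLong and bootstrap
    confidence intervals, repeated stratified cross-validation, operating-point
    reporting), and a synthetic multi-view cohort generator for end-to-end
    testing without access to protected health records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
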