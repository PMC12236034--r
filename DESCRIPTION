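Package: hbpredict
Title: Optimized Clinical Prediction Pipeline for Post-Transplant Haemoglobin Class
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building multiclass clinical prediction models on
    tabular cohorts with heavy, structured missingness. Implements tiered
    missing-value imputation (K-nearest-neighbour filling for
    low-missingness features chained into iterative multilayer-perceptron
    predictive filling for high-missingness features) with a worst-case
    case-block deletion benchmark, adaptive synthetic oversampling (ADASYN)
    for class imbalance, gradient-boosting feature screening wrapped in
    recursive feature elimination, a cluster-similarity ("best
    approximation") procedure for choosing the number of outcome classes,
    error-correcting output-code (ECOC) wrapping of binary and multiclass
    base learners, and a full evaluation stack (stratified splits, tenfold
    stratified cross-validation, macro/micro metrics, mean confusion
    matrices, events-per-predictor). A synthetic cohort generator with a
    latent-factor correlation structure and a three-class haemoglobin
    outcome makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    nnet,
    randomForest,
    e1071,
    xgboost,
    glmnet,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
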