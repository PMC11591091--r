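Package: diabkit
Title: Diet Tracking, Photo-Based Food Weight Estimation, and Stacked
    HbA1c-Change Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mobile-style diabetes management analytics: a food
    composition database with dish aggregation and diet-record nutrient
    accounting; perspective-geometry estimation of shooting distance and
    projected food area from tilted-phone photographs, with a synthetic
    tabletop scene simulator as an independent geometric oracle; LASSO
    regression of food weight on type, tilt angle, distance and projected
    area; a stacked three-class classifier of glycated-hemoglobin (HbA1c)
    change from personal, lifestyle, nutrient-intake and baseline medical
    features, using SMOTE oversampling inside stratified cross-validation
    folds with gradient-boosted trees, a support-vector classifier and
    extremely randomized trees as base learners and a k-nearest-neighbour
    meta learner; model-agnostic Shapley-style feature attribution; and a
    synthetic cohort generator with planted effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    e1071,
    ranger,
    caret,
    yaml,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
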