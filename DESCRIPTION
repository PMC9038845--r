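Package: evotune
Title: Evolutionary Joint Optimization of Features and Hyperparameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-based evolutionary optimizer that jointly evolves
    feature subsets and hyperparameters of a nested machine-learning model
    (elastic-net linear, gradient-boosted trees, or a feedforward neural
    network) under a Bayes Information Criterion fitness with adaptive
    k-fold cross-validation, plateau-based convergence, and a recursive
    warm-start phase that prunes features by importance thresholds derived
    from an elbow analysis. Includes a tabular data-preparation pipeline
    (missingness filtering, winsorizing, non-negative matrix factorization
    imputation, scaling, normality-driven transforms, SMOTE+ENN class
    balancing), permutation feature importances, default-settings baseline
    comparisons, held-out validation, and a synthetic-data generator with
    planted informative features for ground-truth recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    xgboost,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
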