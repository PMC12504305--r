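Package: cfrlbw
Title: Counterfactual Regression and Causal Deep Learning for Low Birth
    Weight Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating heterogeneous effects of a midwife-led
    continuity-of-care (MLCC) intervention on low birth weight from tabular
    mother/newborn cohorts. Implements Pearson chi-square association
    screening, a three-stage feature-selection cascade (univariate screen,
    L1-penalized logistic regression, recursive feature elimination), a
    single-hidden-layer perceptron risk classifier with independent sigmoid
    output units, integral probability metrics between treatment-arm
    representations (Gaussian-kernel maximum mean discrepancy and exact or
    entropically regularized Wasserstein distance), representation-balancing
    counterfactual regression (TARNet, CFR-WASS, CFR-MMD), propensity-score
    baselines with caliper matching, Bayesian ridge and lasso outcome models,
    bagging ensembles, PEHE/ATE/ITE evaluation metrics with bootstrap
    aggregation, and a synthetic potential-outcome cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    pROC,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
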