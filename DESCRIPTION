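Package: qsarscreen
Title: Two-Stage QSAR Screening with Dual-Filter Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-stage quantitative structure-activity relationship (QSAR)
    screening workflow for drug candidate triage. Molecular descriptors are
    reduced by dual-filter feature selection, which fuses mutual-information,
    forest-impurity and boosting-gain rankings by their average rank. A first
    stage regresses compound potency (pIC50) with ensemble tree models
    (bagged forests, gradient boosting, histogram boosting and a cascade
    forest); compounds passing an activity gate proceed to a second stage of
    per-property stacked classifiers with out-of-fold meta-features and a
    Gaussian naive Bayes meta-learner for five binary ADMET endpoints.
    Interpretation utilities provide phi-coefficient association analysis
    with chi-square significance and exact Shapley attributions for the
    boosted-tree activity models. A seeded synthetic-data generator with
    recorded ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    ranger,
    xgboost,
    e1071,
    class,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
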