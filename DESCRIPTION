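Package: pipetree
Title: Genetic Programming Search over Tree-Based Machine Learning Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated machine-learning pipeline optimization for binary
    classification on clinical and metabolomic feature tables. Pipelines are
    expression trees whose leaves are dataset copies, internal nodes are
    feature transformers, selectors and constructors, and whose root is a
    classifier. A genetic-programming search with one-point crossover,
    operator mutation, elitist replacement and a three-way tournament with
    two-way parsimony optimizes ten-fold cross-validated balanced accuracy
    while a Pareto archive tracks the accuracy-complexity trade-off.
    Includes k-nearest-neighbour imputation, stratified splitting,
    grid-search baselines with composed pre-processor chains, permutation
    feature importance, head-ablation sensitivity analysis, and a synthetic
    generator of coronary-artery-disease-like cohorts with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    ranger,
    e1071,
    nnet,
    glmnet,
    xgboost,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
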