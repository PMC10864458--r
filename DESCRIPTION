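Package: algsel
Title: Meta-Learning Algorithm Applicability for Medical Tabular Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tabular classification datasets with 26 statistical and
    information-theoretic characteristic indicators, benchmarks eight classic
    classification algorithms (logistic regression, decision tree, SVM,
    AdaBoost, k-nearest neighbours, naive Bayes, random forest and a
    single-hidden-layer perceptron) for accuracy, runtime and memory with a
    failure taxonomy, discretizes per-dataset accuracy rankings into
    recommendation labels, tests domain differences with an R-by-C chi-square,
    evaluates a bank of 48 published linear formulas predicting log10 runtime
    and memory magnitudes together with domain-scoped applicability rules, and
    re-induces applicability knowledge from metafeature metadata via
    bidirectional stepwise regression and a gain-ratio decision tree with
    pessimistic pruning. Includes synthetic generators for base datasets with
    controllable metafeature structure and for meta-datasets with planted
    rules.
License: MIT
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    foreign,
    nnet,
    rpart,
    randomForest,
    e1071,
    class,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
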