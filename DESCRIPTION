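Package: vssrfe
Title: Variable-Step-Size Recursive Feature Elimination for Gene Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene selection and classification for two-class expression
    matrices (bulk microarray or pseudobulk single-cell). Implements random
    value-based oversampling (RVOS) for class imbalance, an L1-regularized
    squared-hinge linear support vector machine trained by cyclic coordinate
    descent (LLSVM), and recursive feature elimination with a variable step
    size (VSSRFE) that halves the elimination step as the surviving gene set
    halves. Includes per-gene standardization and three-level discretization,
    stratified k-fold cross-validation with grid search, classification
    metrics (accuracy, Matthews correlation coefficient, rank-based AUC),
    and a synthetic expression-data generator with planted informative genes
    so every component is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    foreign,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    class,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
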