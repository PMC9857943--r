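Package: rifsvm
Title: Relative Density-Based Intuitionistic Fuzzy Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fuzzy support vector machines for imbalanced binary
    classification in the presence of noise and outliers. Implements the
    relative density-based intuitionistic fuzzy SVM (RIFSVM), which derives
    per-instance membership and non-membership degrees from k-nearest-neighbor
    relative density estimates, combines them through an intuitionistic fuzzy
    score function, and rescales majority-class weights by the imbalance
    ratio before solving a per-sample-weighted soft-margin SVM dual.
    Also provides the kernel-centroid intuitionistic fuzzy SVM baseline,
    synthetic imbalanced data generators (Gaussian cluster mixtures and
    concentric rings), imbalance-aware evaluation metrics (G-Mean, F-Measure,
    AUC) with a repeated-holdout protocol and cross-validated hyperparameter
    search, and rank-based multi-classifier comparison via the Friedman test
    with Nemenyi post-hoc critical differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    e1071,
    kernlab,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
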