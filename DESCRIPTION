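Package: pepstack
Title: Stacked Ensemble Classification of Anticancer Peptides from
    Sequence and Profile Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies anticancer peptides (ACPs) from amino-acid
    sequences with a two-stage stacked ensemble. Nineteen feature
    encodings -- amino-acid composition (k-mer, distance-based residue
    pairs, reduced-alphabet distance pairs), physicochemical
    autocorrelation (auto/cross/auto-cross covariance, physicochemical
    distance transformation), pseudo amino acid composition (parallel,
    series, and general variants), and eight profile-based encoders
    driven by position-specific scoring matrices -- each feed a
    gradient-boosted tree model whose positive-class scores form a
    meta-feature vector that a grid-searched RBF support vector machine
    turns into the final call. Includes the evaluation protocol
    (sensitivity, specificity, accuracy, Matthews correlation
    coefficient, ROC/AUC, repeated stratified cross-validation, DeLong
    comparison of paired ROC curves) and a synthetic peptide/PSSM
    generator for self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
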