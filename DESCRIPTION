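Package: ms1screen
Title: Module-Based Screening of MS1-Only Feature Intensity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening framework for label-free MS1 feature intensity
    matrices that does not depend on MS/MS identification. Aligned feature
    intensities are quartile-masked, prevalence-filtered, kNN-imputed,
    median-of-ratios normalized and log2 transformed; robust feature modules
    are then found by consensus independent-component analysis followed by
    k-medoid clustering with silhouette-based model selection. Each module is
    summarized by an eigenfeature (first singular direction), eigenfeatures
    are correlated with experimental conditions, and conditions are clustered
    by average linkage with multiscale-bootstrap AU/BP support. Utilities
    include dendrogram comparison by cophenetic correlation with a
    permutation test, Lasso-guided marker selection with leave-one-out
    cross-validation, and a synthetic-screen generator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    cluster,
    glmnet,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
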