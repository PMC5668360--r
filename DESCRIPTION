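Package: fieldblup
Title: Spatially Adjusted Genomic Prediction for Large Breeding Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction for large inbred breeding panels phenotyped in
    non-replicated field trials with repeated checks. Fits REML linear mixed
    models with separable AR1-by-AR1 spatial plot error, block effects and
    either a total genetic effect or an additive (scaled genomic relationship
    matrix) plus residual genetic decomposition; back-solves SNP marker
    effects and their outlier statistics, selects putative QTL with a genetic
    map exclusion window, and compares genome-wide and QTL-based prediction by
    fivefold cross-validation under two accuracy definitions. Also provides
    consensus genetic map scaling, map summary statistics, linkage
    disequilibrium decay analysis, minor allele frequency filtering,
    k-nearest-neighbour genotype imputation, additive and residual genetic
    trait correlations, and a synthetic breeding-panel generator (map-driven
    meiosis, selfing, multi-trait genetic architectures and an AR1-correlated
    trial error field) so the full pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
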