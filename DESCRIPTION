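Package: kronbind
Title: Kronecker Kernel Regression and Benchmarking for Drug-Kinase
    Binding Affinity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative drug-kinase binding affinity (pKd)
    prediction and blinded benchmarking. Implements Kronecker kernel
    regularized least squares (KronRLS) with a closed-form solver for
    complete label matrices and a conjugate-gradient solver for sparsely
    labelled compound-kinase pairs, Tanimoto/Dice fingerprint kernels and
    normalized Smith-Waterman protein sequence kernels, nested
    leave-compound-out cross-validation, grid ensembles and general
    prediction aggregation (mean, median, rank-weighted), a challenge
    scoring suite (RMSE, Pearson, Spearman, concordance index, F1,
    averaged AUC), bootstrap Bayes-factor model comparison with a ladder
    submission protocol, permutation null distributions and
    replicate-based upper bounds, occupancy-based conversion between pKd
    and expected single-dose inhibition, kinase-class enrichment over
    prediction-error rankings, and a synthetic data generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
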