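Package: sigcv
Title: Cross-Validated Selection of the Number of De Novo Mutational Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects the number of de novo mutational signatures in somatic
    mutation count matrices by unsupervised cross-validation of a Poisson
    non-negative matrix factorization model. Balanced cell-wise hold-out
    patterns make K-fold cross-validation feasible for count matrices; an
    expectation/conditional-maximization (ECM) algorithm imputes held-out
    cells while estimating signature profiles and activities, and the rank
    minimizing the held-out generalized Kullback-Leibler prediction error is
    selected. Also provides fixed-rank signature extraction, cosine-similarity
    annotation against a reference catalog, hypermutator filtering, and
    Poisson-model simulators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    parallel
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
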