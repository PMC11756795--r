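Package: transptlr
Title: Robust Transfer Learning for High-Dimensional Linear Regression
    with t-Distributed Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Penalized linear regression with t-distributed errors (PtLR)
    fitted by an EM algorithm on the gamma-normal hierarchy, with l1
    regularization for variable selection in high dimensions. Implements a
    three-step transfer learning estimator that borrows strength from
    auxiliary source datasets (Trans-PtLR), a cross-validation procedure
    that detects which sources are transferable so that unrelated sources
    do not cause negative transfer, Gaussian-error counterparts
    (PNLR/Trans-PNLR), and a simulation engine for benchmarking the
    methods under normal, t, contaminated-normal and skew-t error
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
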