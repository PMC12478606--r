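Package: remirt
Title: Regularized Multidimensional Item Response Models for Multi-Group
    DIF Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits regularized explanatory multidimensional item response
    theory (re-MIRT) models for detecting differential item functioning
    (DIF) across multiple groups. Estimation uses a multi-group Gaussian
    variational EM algorithm (GVEM) with closed-form updates and a Lasso
    penalty on group-specific DIF parameters, optionally refined by an
    importance-weighted variational step optimized with Adam and proximal
    soft-thresholding (IW-GVEMM). The tuning parameter is selected by BIC
    or a generalized information criterion, with a debiasing refit of the
    selected sparsity pattern. Includes a simulator for multi-group DIF
    study designs, DIF effect sizes (weighted area between item response
    curves), detection scoring, and a small-dimension Gauss-Hermite
    quadrature likelihood used as an independent check.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
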