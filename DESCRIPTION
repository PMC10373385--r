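Package: ctref
Title: Individual-Specific Cell-Type Reference Panels from Longitudinal Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deconvolution of repeatedly measured bulk RNA-seq (or other
    admixed omics) into individual-specific, cell-type-specific expression
    reference panels using a linear mixed-effect model estimated by an
    expectation-maximization (EM) algorithm, with likelihood-ratio tests for
    cell-type-specific differential expression in group mean and in temporal
    slope. Includes a Dirichlet-Gamma-Poisson generative simulator of
    longitudinal bulk counts with known ground truth, a surrogate
    signature-based proportion estimator, and evaluation metrics (NMSE, TDR,
    ROC/AUC, sensitivity/FDR, KS uniformity) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    pracma,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
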