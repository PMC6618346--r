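Package: spcafuse
Title: Sparse Principal Component Analysis with Cross-Validated Model
    Selection and CCA Fusion for Multimodal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-one sparse principal component analysis (sPCA) by alternating
    L1-constrained power iterations with sequential deflation, split-sample
    ten-fold cross-validation with an AIC criterion to select the sparsity
    tuning parameter and the number of components, and a canonical correlation
    analysis (CCA) fusion stage linking two subjects-by-features modalities
    (sPCA+CCA). Includes simulation generators with PSNR-calibrated noise and
    Gaussian FWHM smoothing, evaluation metrics (component similarities,
    canonical-correlation error, ROC/AUC, Welch t-tests), a PCA+CCA baseline,
    covariate residualization, delimited-matrix input/output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
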