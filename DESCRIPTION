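Package: vbmnet
Title: Multitask 3D Convolutional Networks for Voxel-Based Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for estimating age, gender and diagnostic
    status from voxel-based-morphometry (VBM) gray- and white-matter density
    volumes with a multitask 3D convolutional neural network. Provides a
    synthetic VBM-like cohort generator with injectable regional effects, NIfTI
    and binary record input/output with background masking and pad-to-cube
    preprocessing, a from-scratch 3D CNN engine (batch normalisation,
    convolution, max-pooling, dropout, Adam) with a joint regression and
    classification objective, stratified k-fold cross-validation with
    train/validation/test rounds, per-task model checkpointing with custom
    early stopping, regression and classification metric suites with ROC
    operating-point selection, SmoothGrad attention maps with brain-atlas
    region-of-interest ranking, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
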