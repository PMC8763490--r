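Package: pulmostage
Title: Lung Nodule Segmentation, TNM Staging and Stage Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale pipeline for lung tumor analysis on CT-like images:
    a region-based active-contour (level-set) nodule segmenter driven by a
    kernel-weighted Mumford-Shah energy, nodule measurement (equivalent
    diameter, voxel count, roundness, solidity type), deterministic TNM
    category and stage-group assignment, a from-scratch multilayer
    convolutional network for stage classification, and a stratified k-fold
    evaluation harness. A synthetic phantom generator produces slab images
    with embedded nodules, ground-truth masks and stage labels so the whole
    pipeline is testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
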