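Package: bioimagedl
Title: Deep Learning Pipeline for Biomedical Image Segmentation,
    Regression and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, configuration-driven pipeline for four common
    biomedical image analysis tasks: semantic segmentation, instance
    segmentation, pixel-wise regression (in-silico staining) and image
    classification. Ships a compact CPU deep-learning core (padded-convolution
    U-Net with encoder dropout, residual classifiers with dropout, Adam,
    early stopping), paired online data augmentation, transfer learning with
    layer-wise weight matching, Monte-Carlo-dropout uncertainty
    quantification, Otsu thresholding, instance mask generation from binary
    ground truth, bootstrap-based quantitative evaluation, and a synthetic
    microscopy-like fixture generator so the whole pipeline runs on a desktop
    CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
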