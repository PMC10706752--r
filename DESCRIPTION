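Package: abisa
Title: Attention-Based Image Sequence Analysis for Whole-Slide Histopathology Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tile-level classification and slide-level risk stratification of
    whole-slide histopathology images with a hybrid patch-transformer + LSTM
    classifier (an attention-based image sequence analyzer). Provides slide
    tiling with entropy/variance rejection of low-information (white) tiles,
    a deterministic synthetic histology-tile generator for end-to-end testing,
    stratified 70-10-20 dataset splitting with affine image augmentation, the
    classifier itself (patch extraction, patch encoding with positional
    embeddings, multi-head self-attention blocks, an LSTM sequence head and a
    GELU multi-layer perceptron) trained by backpropagation with decoupled
    weight decay, a full binary classification metric battery (MCC, Cohen's
    kappa, balanced accuracy, Youden's J, G-mean, Brier score, log loss, ROC
    AUC), and threshold-based aggregation of tile calls into a recurring /
    non-recurring slide decision.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    EBImage
Config/testthat/edition: 3
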