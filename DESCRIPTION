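Package: spineseg
Title: Modular U-Net Ensembles for Multi-Parametric Lumbar Spine MRI Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A modular framework for multi-class semantic segmentation of
    paired sagittal T1w/T2w lumbar-spine MR slices. Networks are assembled
    from interchangeable building blocks (U-Net, VGG-style and dense
    convolutional blocks, multi-kernel input, attention gates, three deep
    supervision variants) into a registry of thirteen encoder-decoder
    topologies trained with per-patient cross-validation splits.
    Variable-size slices are handled by overlapping fixed-size patches whose
    softmax score maps are reconstructed by overlap averaging. Predictions
    are labeled per pixel by maximum a-posteriori probability or by a
    per-class threshold cascade tuned on validation data, ensembles combine
    members by arithmetic or geometric score averaging or by a trainable
    stacking head, and segmentations are scored with per-class IoU,
    precision, recall and F1 plus Wilcoxon signed-rank model comparison.
    A synthetic two-channel spine phantom generator makes the whole pipeline
    runnable without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
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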