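Package: brightcell
Title: Cell Detection from Brightfield Z-Stacks with Iterative
    Unsupervised Domain Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts cells in label-free brightfield focus
    stacks (z-stacks). A reduced U-Net fully convolutional network is
    trained on three consecutive focal planes to regress a per-pixel
    cell-confidence heatmap from point annotations rasterized as small
    disks. A model trained on one annotated cell line is transferred to
    unseen cell lines by iterative unsupervised domain adaptation:
    peaks of the current model's predictions on unlabeled target-domain
    images are converted to pseudo training targets and mixed 50/50
    with the annotated source data over six retraining cycles. Includes
    distance-based detection matching (precision, recall, F1 with a
    closest-match rule), kernel-density-stratified accuracy profiles,
    and a synthetic through-focus stack simulator with source-like and
    target-like domain presets so the whole pipeline can be exercised
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
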