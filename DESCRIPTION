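Package: tilquant
Title: Explainable Computational Scoring of Tumor-Infiltrating Lymphocytes in H&E Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Panoptic segmentation and scoring of tumor-infiltrating
    lymphocytes (TILs) in hematoxylin-and-eosin histology. Implements a
    two-resolution U-Net pair with a cross-branch context hook and a
    region-constrained nucleus classifier driven by compatibility kernels
    and learned region-nucleus priors; masked Macenko stain deconvolution
    and tile informativeness ranking; a whole-slide pipeline with cyclic
    model ensembling; stromal TIL score variants (nTSa, nTnS, nTnA) with
    global and saliency-weighted aggregation and visual-score calibration;
    hospital-stratified internal-external cross-validation metrics; and a
    synthetic H&E generator with exact ground truth so the full pipeline is
    testable without external slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
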