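Package: wristseg
Title: Edge-Detection and PSO-SVM Segmentation for Wrist MRI-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible toolkit for segmenting lesions in two-dimensional
    wrist MRI-like images. Implements a from-scratch Canny edge detector
    (Gaussian smoothing, gradient field, non-maximum suppression,
    double-threshold hysteresis linking), a kernel support vector machine
    trained by an SMO-style dual solver with particle-swarm hyperparameter
    tuning, a synthetic wrist-phantom generator with exact ground truth, and a
    segmentation quality battery (PSNR, MSE, Pratt figure of merit, SSIM, edge
    continuity and credibility indices, accuracy, sensitivity, specificity and
    Dice similarity coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
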