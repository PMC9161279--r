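Package: leafseg
Title: Two-Stream Segmentation and Leaf Counting for Rosette Plant Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based phenotyping of rosette plants (e.g. Arabidopsis) from
    top-down photographs. Implements a two-stream convolutional framework: a
    five-level encoder-decoder with nested dense skip pathways segments the
    whole plant from the background, trained with a combined binary
    cross-entropy and Dice objective (optionally weighted by a boundary
    distance map), and a residual regression network estimates the leaf count,
    using the segmented binary mask as an auxiliary input cue to suppress
    soil, moss and pot clutter. Includes a seeded synthetic rosette image
    generator with exact ground-truth masks and counts, paired image/mask
    augmentation, and the standard evaluation metrics (IoU, precision, recall,
    DiC, ADiC, MSE). All network kernels (convolution, pooling, bilinear
    upsampling) and a small reverse-mode autograd engine are implemented in
    C++ via Rcpp, so the package runs on a plain CPU with no external
    deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
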