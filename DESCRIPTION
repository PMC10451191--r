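Package: waresunet
Title: Weighted Attention Residual U-Net for Long-Tailed Multi-Class Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-class semantic segmentation toolkit for grayscale medical
    images with severely imbalanced (long-tailed) class frequencies. Implements
    a residual U-Net whose bottleneck blocks carry a normalized channel
    attention gate and whose skip connections pass through a 7x7 spatial
    attention bridge, together with an image-count based class rebalancing
    weight formula for the segmentation loss, per-class IoU, sensitivity and
    precision evaluation, a seeded synthetic long-tailed dataset generator,
    a native CPU training loop, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
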