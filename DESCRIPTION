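Package: rhizoseg
Title: Automated Soil-Root Image Segmentation and Root Trait Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated segmentation of plant roots in noisy soil images
    using a patch-based U-Net encoder-decoder network, together with the
    surrounding pipeline: zero-padding and 256x256 patch tiling with exact
    stitch-back, mask dilation and class-balance filtering for dataset
    construction, native network training (Adam, binary cross-entropy,
    best-epoch checkpointing on validation Dice), tiled full-image inference
    with probability thresholding, Dice/precision/recall evaluation, a
    12-group catalogue of 75 skeleton-based root phenotypic traits, and a
    synthetic soil-root image generator so every stage can be trained and
    tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    e1071,
    png,
    tiff,
    yaml,
    utils,
    stats,
    tools,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
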