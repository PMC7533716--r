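Package: leukosr
Title: Geometry-Prior Super-Resolution for Leukocyte Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-image super-resolution for stained leukocyte (white blood
    cell) micrographs guided by a semantic geometry prior. A U-net style prior
    network predicts a three-channel parsing map (nucleus, cytoplasm,
    background) from the bicubically upsampled low-resolution luminance; a
    residual super-resolution network conditioned on that map reconstructs the
    high-resolution luminance. The two networks are trained jointly end to end
    with a Charbonnier reconstruction loss plus a binary cross-entropy
    segmentation loss. Includes a seeded synthetic leukocyte image generator
    with exact parsing-map ground truth, MATLAB-compatible bicubic degradation
    (antialiased imresize, BT.601 YCbCr), LabelMe polygon annotation
    rasterization, PSNR/SSIM evaluation on luminance, and an ablation harness
    comparing geometry-prior, none-prior and bicubic reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
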