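Package: fluorodes
Title: Dual-Energy Subtraction Synthesis and Markerless Tumor Tracking for Simulated kV Fluoroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired single-energy and dual-energy subtraction (DES)
    fluoroscopy from a four-dimensional digital thorax phantom, trains a
    residual U-Net to synthesize bone-suppressed DES images from single-energy
    frames, adjusts clinical-style frames toward the simulated domain
    (affine registration, histogram matching, median smoothing), and
    quantifies markerless tumor-tracking gains with normalized
    cross-correlation template matching, RMSE/TSR statistics, PSNR/SSIM
    image-quality metrics, and paired bootstrap tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
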