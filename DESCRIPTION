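Package: mrforge
Title: Simulation and Multi-Task Correction of MRI Image Artefacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A toolchain for studying MR image quality: physics-motivated
    simulators for the four dominant 2-D MRI artefacts (multiplicative bias
    fields drawn from a Gaussian spatial random field, Cartesian k-space
    subsampling with fastMRI-style and centered masks, rigid and periodic
    respiratory motion injected as k-space phase errors, and complex Gaussian
    k-space noise at a prescribed SNR); a convolutional loss family built
    from a bank of nine edge-detection kernels; a label-masked multi-task
    residual loss; a dual-domain (image plus k-space) residual correction
    network with four artefact-specific output heads, trainable on CPU at
    reduced scale; image-quality metrics (MSE, SSIM, pixel-domain VIF); and
    a seeded synthetic phantom generator so the whole pipeline is testable
    without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rhdf5,
    RNifti,
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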