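Package: spinesynth
Title: MR-to-CT Spine Translation with Conditional Denoising Diffusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for paired MR-to-CT translation of sagittal spine
    imaging with conditional denoising diffusion implicit models (DDIM).
    Provides vertebra-landmark rigid registration (1- and 2-point centre-of-
    mass modes with iterative translate-and-segment refinement), intensity
    normalisation and elastic augmentation, 2D self-attention U-Net and 3D
    attention-free fully-convolutional denoisers with noise- and image-
    prediction modes, classifier-free guidance, spine-masked image-quality
    metrics (PSNR, SSIM, VIFp, L1, MSE) and per-vertebra Dice evaluation,
    plus a synthetic spine-phantom generator that makes the whole pipeline
    testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
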