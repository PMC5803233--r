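Package: tomodenoise
Title: Projection-Domain CNN Enhancement for Low-Dose X-Ray Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enhances low-dose (short-exposure) X-ray tomographic projections
    with an encoder-decoder convolutional neural network trained on a few
    low/high-dose projection pairs of the same object, then applied to the
    full angular scan. Includes a synthetic sphere-in-cube phantom benchmark
    with a parallel-beam Radon projector and percentage-scaled Gaussian noise,
    two-step image normalization with overlapping patch extraction and
    reassembly, a Parzen-filtered Fourier/backprojection reconstructor,
    median-filter and total-variation denoising baselines, and PSNR/SSIM/
    histogram image-quality evaluation with tidy per-slice reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
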