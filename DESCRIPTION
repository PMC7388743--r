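Package: aggdenoise
Title: Wavelet Shrinkage De-Noising with Adaptive Generalized Gaussian
    Threshold Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wavelet-domain de-noising of 2-D grayscale images (MRI brain
    slices are the intended use case) with a family of shrinkage functions:
    the classical hard and soft thresholds, Zhang's smooth soft/hard
    variants, adaptive hard/soft functions that tune sub-threshold
    coefficients through an adaptive generalized Gaussian distribution
    (AGGD) core instead of zeroing them, and the improved AGGD function
    with sigmoid-weighted outer branches. Includes MAD-based noise
    estimation from the finest diagonal subband, VisuShrink and
    AGGD-intersection threshold selection, an orthonormal periodized
    Daubechies filter bank, PSNR/MSE quality metrics, a brain-like phantom
    generator with additive white Gaussian noise simulation, a benchmark
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
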