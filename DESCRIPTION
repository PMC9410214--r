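Package: hexatrellis
Title: Virtual Hexagonal Trellis Filtering for Blood-Smear Image Enhancement
Version: 0.1.0
Authors@R:
    person("hexatrellis", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Enhancement of white-blood-cell smear images with a 3x3
    convolution kernel derived from a virtual hexagonal trellis laid over
    the square pixel grid. Provides the preprocessing chain used before
    filtering (image complement, dark-channel dehazing, grayscale
    conversion), the symbolic derivation of the hexagonal-trellis kernel
    for any constant filter factor, a single-stride convolution engine
    with explicit border and rounding contracts, a full-reference and
    no-reference image quality metric suite (MSE, PSNR, SSIM, NCC, NAE,
    MAE, entropy, EME, alpha rooting), classical comparator filters
    (histogram equalization, mean, adaptive Wiener), a seeded synthetic
    smear-image generator for dataset-free testing, and a command-line
    interface with experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
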