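Package: ovatex
Title: Texture-Based Classification of Ovarian Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discriminating benign-like from
    malignant-like texture in grayscale (contrast-enhanced) ultrasound
    images: 2-D discrete wavelet decomposition and soft-threshold
    denoising, multiscale rotation-invariant uniform local binary
    pattern (LBP) descriptors, Laws' texture-energy features, and a
    logistic-regression classifier fitted by Newton-Raphson maximum
    likelihood with confusion-matrix evaluation. Includes a synthetic
    speckle-texture generator for reproducible benchmarking, noise
    injection utilities, and contingency-table statistics for the
    accompanying clinical summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
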