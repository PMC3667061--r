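Package: cawave
Title: Calibration and Velocimetry of Propagating Calcium Waves from
    Ratiometric Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic calibration and characterization of propagating
    intracellular calcium waves recorded as interlaced two-filter (Fura-2
    340/380 nm) fluorescence image sequences, or as a single 380 nm stream at
    higher frame rates.  Provides Fourier phase-correlation frame registration
    with starlet (a-trous) wavelet prefiltering, ratiometric calcium index
    computation, exponential marker-decay correction, sigma-clipped basal
    estimation, wave extraction with per-pixel statistics, morphological
    signal masking, automatic propagation-source localization, radial
    ring-profile reduction, robust linear velocity fits, and Heaviside-gated
    decay-model fitting (Levenberg-Marquardt), both per radial distance and
    per pixel.  A synthetic-experiment generator with known ground truth
    supports validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
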