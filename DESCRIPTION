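Package: contourscope
Title: Lensless Mesoscopic Fluorescence Imaging: Mask Design, Shift-Variant
    Reconstruction and Widefield Calcium Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for a mask-based lensless mesoscope.
    Designs 'contour' phase masks (Perlin-noise contour targets, angular-spectrum
    phase retrieval, fabrication-step quantization), simulates image formation
    with depth-indexed and laterally varying point spread functions, reconstructs
    scenes by closed-form Wiener/Tikhonov deconvolution or FISTA with a jointly
    estimated low-frequency (DCT-constrained) background, and implements the
    downstream widefield calcium-imaging analyses: blank subtraction, dF/F,
    rigid registration, retinotopic position tuning via Gaussian fits, and
    orientation-column mapping (stimulus-harmonic amplitude maps, spatial
    bandpass, d-prime decoding with cross-validation, pairwise map correlations,
    vector-summation composite maps and label-shuffle null distributions).
    Includes synthetic phantoms (USAF-1951 target, orientation-column cortex
    with stimulus-entrained GCaMP dynamics and heartbeat artifact) so the whole
    pipeline is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
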