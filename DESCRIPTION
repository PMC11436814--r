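Package: eemda
Title: Domain-Adapted Deep Regression and Occlusion Interpretability for
    Fluorescence Excitation-Emission Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts olive-oil oxidation quality indicators (the UV
    extinction coefficients K232 and K268) from fluorescence
    excitation-emission matrices (EEMs) by two-phase domain adaptation of
    an image-regression backbone, and localises the spectral bands that
    drive the predictions with an occlusion-based information elimination
    algorithm. Includes EEM CSV input/output, backbone-ready image
    preprocessing with exact wavelength-to-pixel maps, oil-grouped
    leave-one-out cross-validation, a trainable stand-in convolutional
    backbone for fully offline use, and a synthetic EEM generator with
    coupled quality-indicator labels so the complete pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    withr,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
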