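Package: seizpipe
Title: Multimodal EEG/fMRI Seizure-Detection Pipeline with Adaptive
    Denoising, Enhanced CSP and S-PHOG Features, and Soft-Voting Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for epileptic seizure detection from multichannel EEG and
    brain images. Implements a Gauss-based median filter (G-MF) for signals and
    an adaptive weight-based Wiener filter (AW-WF) for images, handcrafted EEG
    descriptors (Welch band powers, Hjorth parameters, line length,
    zero-crossing rate, spectral roll-off), an enhanced common spatial pattern
    (E-CSP) spatial filter bank with covariance shrinkage and frequency
    weighting, a smoothed pyramid histogram of oriented gradients (S-PHOG)
    image descriptor, a compact seed-deterministic volumetric embedder, a
    dual-branch attention convolutional classifier plus a lightweight
    ghost-feature network fused by soft voting, reconstruction-quality and
    classification metrics, subject-independent cross-validation, and fully
    reproducible synthetic EEG/phantom generators for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    png
Config/testthat/edition: 3
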