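Package: msstm
Title: Source Microstate Analysis and Style Transfer Mapping for
    Cross-Subject EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for cross-subject emotion recognition from
    multi-channel EEG. Implements distributed source localization with
    sLORETA standardization, global-field-power (GFP) peak microstate
    clustering with GEV and cross-validation model selection,
    microstate statistical features (coverage, duration, occurrence,
    transition probabilities) over five frequency bands, differential
    entropy and band-power baselines, style transfer mapping (a
    confidence-weighted regularized affine domain adaptation), and a
    leave-one-subject-out evaluation protocol with linear SVM
    classifiers. Ships a synthetic EEG generator with known microstate
    ground truth so the full pipeline is testable without access to
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
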