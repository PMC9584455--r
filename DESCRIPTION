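Package: structrf
Title: Structured Random Receptive Fields for Random Feature Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generative Gaussian-process models of sensory receptive fields
    with structured covariance functions (bandlimited temporal covariances for
    insect campaniform sensilla, localized Gaussian-windowed covariances for V1
    simple cells), tools to sample structured weight banks via the
    Karhunen-Loeve eigenbasis, random feature networks that use those weights
    with a squared-hinge linear SVM readout, covariance-model fitting to
    measured receptive-field populations by normalized Frobenius distance,
    spectral diagnostics, synthetic frequency-detection and frequency-XOR
    benchmark tasks, and structured initialization for fully trained
    single-hidden-layer networks.
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
    e1071,
    optparse
Config/testthat/edition: 3
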