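Package: sleepcontrast
Title: Contrastive Signal-Label Embedding for Single-Channel EEG Sleep Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a dual-encoder contrastive model for automatic sleep
    staging from single-channel EEG. Thirty-second signal epochs are embedded
    by a multi-scale 1-D convolutional encoder with channel and spatial
    attention, categorical AASM stage labels (W, N1, N2, N3, REM) are embedded
    by a small pre-norm transformer with a class token, and the two encoders
    are trained jointly by a symmetric cross-entropy objective over the matrix
    of pairwise cosine similarities. Epochs are classified at inference by
    nearest label prototype. Also provides EDF/EDF+ reading and writing with
    hypnogram expansion, median-filter baseline correction and epoch
    preprocessing, accuracy and macro-F1 evaluation, and a seeded synthetic
    polysomnography generator with stage-dependent spectral content so the
    whole pipeline can be exercised without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
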