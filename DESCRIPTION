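Package: ffatune
Title: Farmland Fertility Optimised CNN-GRU Classification of ECG Beats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for automated arrhythmia classification from
    fixed-length ECG beat windows: z-score standardisation, a hybrid one
    dimensional convolutional / gated recurrent unit (CNN-GRU) classifier
    trained by mini-batch gradient descent, and hyperparameter tuning with
    the Farmland Fertility Algorithm (FFA), a sectioned population
    metaheuristic with global and local elite memories, driven by
    cross-validated classification error. Includes a seedable synthetic ECG
    beat generator for fully reproducible desk-scale experiments and a
    minimal WFDB adapter for annotated Holter records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
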