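Package: ztwbes
Title: Zero-Time-Windowing Epoch Selection and Adaptive Electrode
    Relevance for EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Subject-adaptive EEG emotion recognition built around
    zero-time windowing (ZTW) and the numerator group-delay (NGD)
    spectrum. Implements ZTW-based epoch selection (ZTWBES) with
    per-electrode plurality and cross-electrode majority voting,
    baseline-relative identification of relevant electrodes per subject,
    emotion and frequency band, feature extraction as relative band-energy
    changes, quadratic discriminant and Levenberg-Marquardt-trained
    neural classifiers with one-vs-all vote fusion, leakage-free
    cross-validated experiment pipelines, and a ground-truthed synthetic
    emotional-EEG generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
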