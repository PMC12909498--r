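Package: fatigueFusion
Title: Multimodal EEG-ECG Fatigue Detection with Two-Stage Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for detecting operator fatigue from short (2-second)
    segments of multichannel EEG and single-channel ECG. Recordings are
    band-pass filtered (0.5-30 Hz), decomposed into the delta, theta, alpha
    and beta bands by brick-wall FFT masking, and cut into overlapping
    epochs. Eight spectral/time-domain features per EEG channel-band and
    seven statistical moments per ECG epoch are z-scored within subject,
    screened by one-way ANOVA, and the most discriminative EEG channels are
    ranked by the cross-validated AUC of per-channel linear support vector
    machines. The fused low-dimensional feature set is classified with
    gradient-boosted trees under both epoch-shuffled (cross-clip) and
    subject-disjoint (cross-subject) cross-validation. A seeded synthetic
    cohort generator with known injected band-power and ECG-moment effects
    supports calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    xgboost,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
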