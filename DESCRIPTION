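Package: foodcue
Title: Intracranial EEG Analysis of Food Anticipation and Consumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stereo-EEG recordings collected while
    subjects anticipate and consume food, centred on high-frequency broadband
    (70-170 Hz) envelope dynamics in the insulo-opercular cortex. Provides the
    full signal chain (notch filtering, flanking-Laplacian re-referencing,
    Hilbert band-power extraction, epoching with pooled-baseline z-scoring),
    cluster-based permutation statistics against baseline and between
    conditions, layered classification of recording sites as inactive,
    responsive or condition-specific, single-trial response onset latency
    estimation, weighted k-nearest-neighbour single-trial decoding with
    permutation feature importance, inter-ictal spike detection and
    spectrum-matched interpolation for ad libitum meal recordings, and a
    synthetic SEEG generator with planted ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    pROC,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
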