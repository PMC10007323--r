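Package: emgica
Title: Crosstalk Simulation and Reduction in Facial EMG Using Infomax ICA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying and removing volume-conduction crosstalk in
    multichannel facial surface electromyography (EMG). Simulates cohorts of
    four-channel facial EMG recordings (corrugator supercilii, zygomatic
    major, masseter, suprahyoid) with a known distance-dependent mixing
    matrix; preprocesses raw signals to 10 Hz rectified (average rectified
    value) envelopes; decomposes per-participant envelope matrices with
    infomax independent component analysis; reconstructs crosstalk-reduced
    signals from the components carrying the highest variance share on the
    emotion-sensing channels; and runs the associated statistical battery
    (one-sample and paired t-tests, Wilcoxon signed-rank tests, Holm
    step-down correction, noncentral-t power analysis).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
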