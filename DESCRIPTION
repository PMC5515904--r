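Package: interopipe
Title: Electrophysiology of Interoceptive and Exteroceptive Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for heartbeat-detection
    experiments combining scalp EEG, ECG, keypress tracking, and depth
    (intracranial) recordings. Provides a ground-truth synthetic generator
    (ECG with R peaks, 128-channel scalp EEG with cardiac-field artifact and
    heartbeat-evoked potential, tapping responses, depth contacts with
    band-power modulations), heartbeat-detection accuracy scoring with
    repeated-measures ANOVA and Tukey post hoc tests, R-locked preprocessing
    and epoching, point-wise Monte-Carlo permutation tests with a
    consecutive-sample run filter, weighted symbolic mutual information
    (wSMI) connectivity with current-source-density transform and distance
    profiles, and baseline z-scored windowed-Fourier time-frequency
    contrasts for intracranial contacts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
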