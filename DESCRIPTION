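Package: auditest
Title: Adaptive Listening-Test Procedures for Remote Auditory Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An offline, scriptable engine for remote hearing tests of the
    kind used with cochlear-implant recipients and other hearing-device
    users: stimulus level calibration and signal-to-noise mixing in dB FS,
    synthesis of digits-in-noise and spectro-temporal ripple (STRIPES)
    style test stimuli, transformed up-down adaptive staircases with
    speech-reception-threshold and reversal-mean estimators, ordered /
    paired / ranked task structures with binary-insertion ranking,
    technical checks including a connection check that detects loudspeaker
    leakage by temporal cross-correlation and amplitude-spectrum
    correlation, trial scoring, CSV manifest and result persistence, and a
    simulated psychometric listener harness that validates every adaptive
    procedure without human participants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
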