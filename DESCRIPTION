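Package: thermosleep
Title: Sleep-Wake States and EEG Oscillations from Cortical Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of the coupling between mouse cortical temperature and
    brain state. Predicts wakefulness, NREM and REM sleep from 10 Hz brain
    temperature traces alone, detects theta-dominated wakefulness from EEG
    with a continuous-wavelet-transform relative theta power criterion,
    quantifies the ~50 s infraslow modulation of sigma/spindle power with
    Lomb-Scargle periodograms, estimates the lag between EEG band power and
    the temperature response by cross-correlation, and aligns temperature and
    spectral changes on state transitions including the cataplexy-associated
    state of hypocretin-deficient mice. Includes a synthetic-recording
    generator with ground-truth parameters for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
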