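Package: ssvepspeller
Title: SSVEP-Driven Cheonjiin Korean Speller: Simulation, CCA Decoding and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free test bed for a two-channel SSVEP (steady-state
    visual evoked potential) brain-computer-interface speller built on the
    Cheonjiin Korean keyboard. Provides a synthetic EEG generator with
    frame-locked flicker schedules, harmonic SSVEP responses, 1/f background,
    alpha rhythm and line noise; the online preprocessing chain (detrend,
    Butterworth band-pass, dual band-stops, 1.5 s sliding windows); canonical
    correlation analysis frequency recognition with channel-wise maximum
    reduction and a threshold/consistency accumulation decision rule; a full
    Cheonjiin Hangul composition automaton with multi-tap consonants and
    heaven-earth-human vowel assembly plus a keystroke-economy planner; and
    evaluation tools (confusion metrics, information transfer rate, amplitude
    spectra, SNR, event-related spectral perturbation) with experiment
    harnesses that replay the single-command and word-typing protocols on
    simulated subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    stringi,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
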