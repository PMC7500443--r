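Package: tacsloop
Title: Simulation and Analysis of Closed-Loop Phase-Locked tACS-EEG Experiments
Version: 0.1.0
Authors@R:
    person("EEG", "Methods Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generative simulator and offline analysis pipeline for intermittent,
    phase-locked transcranial alternating current stimulation (tACS) experiments
    with concurrent EEG. Simulates multi-channel sessions with an individual
    alpha frequency, eyes-open/eyes-closed block structure and a parameterized
    transient post-stimulation alpha suppression; implements the online side
    (Hilbert-based phase estimation, latency-compensated phase forecasting,
    stimulation waveform synthesis) and the offline side (windowed alpha power
    via detrended zero-padded FFT, common spatial patterns with
    leave-one-trial-out cross-validation, repeated-measures ANOVA with
    Greenhouse-Geisser correction, marginal means and polynomial contrasts).
    Includes BrainVision and EDF+ writers/readers and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
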