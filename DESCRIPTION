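Package: infraslow
Title: Infraslow Sigma-Power Dynamics and Arousability Analysis for Mouse
    NREM Sleep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the ~0.02 Hz infraslow fluctuation of
    sleep-spindle (sigma, 10-15 Hz) power during mouse non-rapid eye
    movement sleep and its relation to spontaneous and evoked arousability.
    Implements sigma-power extraction by Morlet wavelets with FIR smoothing,
    Hilbert-phase analysis, trough-peak-trough cycle detection, phase
    coupling of microarousals with circular statistics, phase-binned band
    dynamics, an activation index for local cortical arousals, heart-rate
    extraction from the nuchal EMG, an online vigilance-state machine with a
    continuity/fragility period classifier, and automatic scoring of
    closed-loop vibration trials.  A ground-truthed polysomnography
    generator emulating Sham and spared-nerve-injury (SNI) recordings makes
    every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
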