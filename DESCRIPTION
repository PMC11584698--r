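Package: cardiophase
Title: Cardiac-Phase-Resolved Analysis of Sensorimotor Rhythm Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for studying how the phase of the cardiac
    cycle (ventricular systole versus diastole) at movement-cue onset
    modulates contralateral alpha and beta desynchronization in sensorimotor
    regions and lateralized muscle activity during motor imagery and
    execution. Provides a synthetic generator of coupled
    ECG/neural/EMG sessions with known ground truth, ECG delineation
    (R peaks, T-wave offsets) with cue phase and cycle-angle labelling,
    regression-based cardiac-field artifact removal, Morlet time-frequency
    band power with baseline z-scoring, EMG envelope extraction, timewise
    within-subject sign-flip permutation tests with adaptive two-stage FDR
    control and dependent-samples probability-of-superiority effect sizes,
    and circular (Rayleigh) statistics of cue angles with a Monte-Carlo
    null.
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
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
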