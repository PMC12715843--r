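Package: eegMUAe
Title: Predicting Cortical Multi-Unit Activity Envelopes from Scalp EEG
    Spectrotemporal Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating scalp electroencephalography (EEG) to
    intracortical multi-unit activity envelopes (MUAe) recorded during
    steady-state visually evoked potential (SSVEP) paradigms. Implements
    MUAe extraction from wideband signals (band-pass, rectify, Hilbert,
    downsample), zero-phase FIR band decomposition of EEG into seven
    canonical bands, power-spectrum based electrode selection, amplitude
    and z-score based artifact-trial rejection, phase-amplitude coupling
    via the Kullback-Leibler Modulation Index with circular-shift
    surrogate nulls, and an L1-regularized linear model predicting
    instantaneous MUAe from band amplitudes, circularly linearized band
    phases, amplitude-phase interactions, and optionally the stimulus
    phase, evaluated by nested 5-fold cross-validation. A synthetic-data
    generator with recorded ground truth makes every stage verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
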