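Package: holofield
Title: Neural-Field Modeling and Analysis of Holographic Ensemble Photostimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how small ensembles of layer 2/3 excitatory
    neurons reshape activity in mouse primary visual cortex when driven by
    two-photon holographic optogenetics. Implements a linearized
    two-dimensional neural-field model with joint space- and
    orientation-dependent recurrent wiring, solved exactly in Fourier space
    and via a truncated synaptic-pathway expansion (monosynaptic E-E,
    disynaptic E-E-E and E-I-E terms); a calcium-imaging analysis pipeline
    (dF/F with neuropil subtraction and rolling-percentile baseline,
    orientation tuning and selectivity, exclusion filtering,
    distance-resolved response curves, sum-of-Gaussians center-surround
    fits, bootstrap modulation significance, point-spread-function fits); a
    swap-based discrete optimizer for designing stimulation ensembles; and a
    seeded synthetic-data generator that emulates multi-plane two-photon
    recordings so every stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
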