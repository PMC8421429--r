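Package: hopfbrain
Title: Whole-Brain Phase Dynamics and Hopf Network Models of BOLD Signals
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Phase-synchronization analysis of region-wise BOLD time series
    (instantaneous phases via band-pass filtering and the Hilbert transform,
    phase-interaction matrices, integration, segregation, phase-interaction
    fluctuations and functional connectivity dynamics), together with a
    whole-brain network model of coupled noisy Stuart-Landau oscillators on
    a weighted structural connectome. Provides simulation of the coupled
    Hopf normal form, fitting of the global coupling by Kolmogorov-Smirnov
    distance between functional-connectivity-dynamics distributions,
    node-wise bifurcation-parameter fitting from spectral power proportions,
    effective-parameter decomposition, linear stability analysis of the
    silent fixed point, rich-club and hub analysis of structural
    connectomes, and generators of synthetic connectomes and ground-truth
    BOLD for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
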