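Package: kuradapt
Title: Kuramoto Networks with Adaptive State-Dependent Conduction Delays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and stability analysis of Kuramoto phase-oscillator
    networks whose conduction delays are themselves dynamical variables,
    adjusting to pairwise phase differences as a model of activity-dependent
    myelin plasticity. Provides a fixed-step integrator for the coupled
    phase/delay system of state-dependent delay differential equations,
    estimators for the asymptotic synchronization frequency and phase
    offsets, closed-form root and eigenvalue analysis of the two-oscillator
    network, a Gaussian mean-field (N-limit) stability toolkit based on an
    exponential-polynomial reduction of the characteristic equation, and
    protocols for probing the resilience of synchronization to random
    removal of connections (injury).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
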