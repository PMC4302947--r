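Package: bcpnnsim
Title: Event-Driven Simulation of Spike-Based BCPNN Synaptic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of the spike-based Bayesian Confidence Propagation
    Neural Network (BCPNN) synaptic plasticity rule. Three interchangeable
    engines advance the eight synaptic trace variables: a fixed-step explicit
    Euler integrator and two exact event-driven schemes, one operating on the
    canonical Z/E/P trace cascade and one on a reduced set of purely
    exponentially decaying state variables. Includes look-up tables for
    exponential decay factors, fixed-point storage emulation with analytic
    value-range bounds, a reduced cortical hypercolumn model with soft
    winner-take-all minicolumn units, synthetic Poisson/correlated/regular
    spike-train generators, and accuracy benchmarks (normalized mean absolute
    error against the exact solution) for both integration step size and
    fixed-point word length.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
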