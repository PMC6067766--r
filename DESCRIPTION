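Package: desynctrl
Title: Minimally Invasive Desynchronising Control of Coupled Neuronal Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and control of synchronisation in networks of coupled
    phase oscillators modelling mesoscopic neuronal patches. Implements the
    networked Kuramoto and Stuart-Landau (Hopf normal form) models, the
    Kuramoto order parameter, and a Hamiltonian-control-derived
    desynchronising stimulation scheme: the full theoretical control term,
    its all-to-all simplification, and an operational variant that uses only
    M implanted microelectrodes whose signals spread through an exponentially
    decaying field. Ships small-world (Newman-Watts) and Erdos-Renyi network
    generators, a Proportional-Differential Feedback baseline, seizure-like
    coupling-schedule protocols, and seeded sweep drivers for suppression
    phase diagrams. Time integration uses a fixed-step fourth-order
    Runge-Kutta core written in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
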