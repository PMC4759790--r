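Package: burstswitch
Title: Translational Bursting Noise in Genetic Toggle Switches
Version: 0.1.0
Authors@R:
    person("burstswitch", "developers", email = "burstswitch@example.org",
           role = c("aut", "cre"))
Description: Stochastic modelling of translational bursting in genetic
    toggle switches. Implements a hierarchy of models for a two-gene
    mutual-repression circuit (and a three-way switch with
    self-activation): exact Gillespie simulation of the full
    mRNA-protein model and of three protein-only reductions
    (geometric bursts, constant bursts, no bursts), the Kramers-Moyal
    diffusion approximation of the geometric-burst model, and a
    three-state piecewise deterministic Markov process (PDMP) together
    with its shot-noise limit of instantaneous exponential
    concentration bursts. Provides mean first switching times to the
    symmetric boundary by Monte Carlo for every engine and by a
    finite-difference solution of the shot-noise backward equation,
    quasi-potentials in the weak-noise limit via WKB Hamiltonians and
    a geometric minimum action method, Jensen-Shannon comparison of
    stationary distributions, mode detection, and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
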