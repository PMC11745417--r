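Package: ribonet
Title: Quasi-Steady-State Kinetics of Autocatalytic RNA Replicator Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic simulation of prebiotic RNA replicator ecologies
    built on Michaelis-Menten enzyme kinetics under the Briggs-Haldane
    quasi-steady-state approximation. At every instant the concentrations of
    all n^2 pairwise ribozyme-template complexes are obtained by solving a
    nonlinear mass-balance system with a damped Newton iteration (analytic
    Jacobian; the tight-binding Morrison equation is the one-complex special
    case), and total species concentrations are advanced by explicit Euler
    time stepping under a logistic habitat-capacity restriction. Ships the
    host, host-parasite and host-parasite-hyperparasite model variants as
    runnable presets, a structured text configuration format, trajectory
    export, qualitative outcome classification and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
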