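Package: isocascade
Title: Parallel Instationary 13C Labeling Simulation by Strongly
    Connected Component Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates transient 13C isotope labeling dynamics in
    atom-mapped metabolic networks.  Elementary metabolite unit (EMU)
    reaction networks are traced backward from measured fragments,
    reorganized into a prunable directed network of individual mass
    isotopomers, decomposed into weight-homogeneous strongly connected
    components (SCCs), and assembled into per-SCC isotope balance
    ordinary differential equations in both tensor and vector form,
    with forward sensitivities over free fluxes and pool sizes.
    Integration is by constant-step fourth-order Runge-Kutta or
    adaptive Cash-Karp with a pilot step-size controller, serially or
    under a deterministic dependency-cascade parallel contract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
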