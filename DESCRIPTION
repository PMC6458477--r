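Package: pnpaxon
Title: Poisson-Nernst-Planck Simulation of Transcranial Electrical
    Stimulation at a Node of Ranvier
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Finite-element simulator of ion electrodiffusion around a
    myelinated axon segment during transcranial electrical stimulation
    (TES).  Couples the Poisson-Nernst-Planck equations for sodium,
    potassium, calcium and chloride ions with Hodgkin-Huxley gating
    kinetics applied as membrane flux boundary conditions on a node of
    Ranvier.  Provides a structured, Debye-layer-refined mesh generator
    for the two-dimensional axon geometry, a Gauss-Seidel operator
    splitting time integrator with a backward-Euler Nernst-Planck step,
    per-site gating and flux time series, polarization profiles,
    intracellular ion totals, and a ladder of independent verification
    oracles (manufactured solutions, Boltzmann equilibria, Debye-layer
    profiles and an isolated point-membrane model).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
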