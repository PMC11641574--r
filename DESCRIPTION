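Package: ecrmotor
Title: Mesoscale Simulation of Enzyme-Cascade-Powered Janus Nanomotors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid molecular dynamics / multi-particle collision dynamics
    (MD-MPC, stochastic rotation dynamics) simulator of a Janus colloid
    propelled by a two-enzyme cascade reaction. A bead-spring Janus sphere
    carries an inert hemisphere (E0), a catalytic hemisphere (E1, fuel A to
    intermediate I) and an outer hemispherical shell of a second enzyme
    (E2, I to product B) at tunable coverage. The solvent is a point-particle
    MPC fluid coupled to the motor through purely repulsive shifted-truncated
    Lennard-Jones (WCA) interactions, so self-diffusiophoretic propulsion,
    concentration fields and hydrodynamic flow fields emerge from the
    microcanonical dynamics. Includes observables (axial velocity statistics,
    radial/angular concentration profiles, motor-frame flow fields), the
    coverage power-law velocity fit, analytic MPC transport coefficients,
    deterministic seeded runs with checkpointing, and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
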