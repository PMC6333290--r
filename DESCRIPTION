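Package: promaswim
Title: Boundary-Element Simulation of Monoflagellate Pullers in Shear Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the swimming of a large-bodied monoflagellated puller,
    the virtual Leishmania promastigote, in Newtonian shear flow using a
    boundary element discretisation of the Stokes equations. The swimmer is a
    prolate ellipsoidal body with an attached flagellum beating with a
    prescribed planar travelling wave; free-space and no-slip-wall (Blake
    image system) Green's functions are provided, together with second-order
    time stepping of the rigid-body dynamics, short-range repulsive wall
    forces, phase-averaged reduced dynamics in the bulk and near a plane
    boundary, Jeffery-orbit period fitting, saddle/separatrix phase-plane
    analysis, and guidance of swimmers by time-dependent shear schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    deSolve,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
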