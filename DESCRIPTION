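Package: angioflow
Title: Image-Based Microvascular Flow Simulation and Perfusion Analysis
Version: 0.1.0
Authors@R:
    person("angioflow", "developers", email = "angioflow@example.org",
           role = c("aut", "cre"))
Description: Reconstructs a three-dimensional vascular lumen from a
    two-dimensional binary vessel mask by a union-of-spheres envelope,
    embeds it in a uniform Cartesian grid through a signed-distance
    (level-set) field, solves steady incompressible Newtonian flow with
    a volume-penalization immersed-boundary Navier-Stokes solver
    (staggered grid, SMAC fractional step, RK3/Crank-Nicolson), and
    quantifies transport toward the angiogenic front of a growing
    vascular plexus by azimuthal flow-rate decomposition in a
    cylindrical frame.  Includes vessel morphometrics (vascular density,
    vessel length density, branching index), a synthetic generator of
    artery-capillary-vein wedge networks for end-to-end testing, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
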