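Package: lahemo
Title: Desk-Scale Left Atrial Hemodynamics and Stroke-Risk Biomarkers
Version: 0.1.0
Authors@R:
    person("lahemo", "developers", email = "lahemo@example.org", role = c("aut", "cre"))
Description: Simulates blood flow in a moving left atrium at desk scale and
    derives stroke-risk biomarkers. A synthetic cohort generator produces
    tagged tetrahedral chamber meshes (wall, four pulmonary veins, mitral
    valve, appendage) with frame-wise boundary displacements emulating
    CINE-derived motion; a periodic smoothing-spline temporal model and a
    stiffened harmonic lifting extend the motion into the volume; a
    stabilized P1-P1 finite-element solver integrates the incompressible
    Navier-Stokes equations in Arbitrary Lagrangian-Eulerian form with
    switching mitral-valve boundary conditions and backflow stabilization.
    Post-processing computes phase-averaged velocity, flow stasis, wall
    shear stress statistics (TAWSS, OSI, RRT, ECAP), kinetic energy,
    enstrophy, appendage tortuosity and ostium area, and merges hemodynamic
    medians with functional metrics through penalized logistic regression
    to assess the separation of stroke from control phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    mgcv,
    igraph,
    jsonlite,
    xml2,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
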