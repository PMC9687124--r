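Package: palpsim
Title: Finite-Element Palpation Simulation and Neural-Network Stress Surrogates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for simulating two-finger abdominal palpation
    and learning real-time surrogates of the resulting liver stress field.
    Builds a parametric voxel phantom (flesh block, rib bars, ellipsoidal
    liver), runs an explicit hexahedral finite-element solver with Ogden
    visco-hyperelastic liver tissue, Prony-series stress relaxation,
    piecewise-linear-plastic ribs and rigid-finger penalty contact, sweeps
    palpation locations to build a training dataset, and trains a
    multilayer-perceptron surrogate that maps palpation position and contact
    force to the maximum-principal-stress field on the liver edge. Includes a
    software force-plate pipeline that resolves contact position from four
    corner force sensors and renders colour-mapped stress frames.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
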