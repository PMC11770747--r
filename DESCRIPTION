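Package: phototherm
Title: Photothermal Nanoparticle Benchmarking and Tissue Heating Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for benchmarking plasmonic nanoparticle photoheaters and
    predicting the heating they can deliver at depth in tissue. Estimates the
    photothermal conversion efficiency (eta) of a nanoparticle suspension from
    heating/cooling thermal traces via the lumped-capacitance energy balance
    and Newton-cooling time-constant fit, and the mass-normalized efficiency
    (eta_m, heat per microgram of nanoparticle in the beam path) from
    short-exposure heating slopes. Includes a seeded generator of synthetic
    thermal traces for estimator validation, a voxel Monte Carlo simulation of
    near-infrared (808 nm) photon transport in a homogeneous breast-tissue
    slab, and an idealized voxel heating model combining the two to predict
    ramp times from body temperature to the 43 degree hyperthermia threshold
    at 0-30 mm depth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
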