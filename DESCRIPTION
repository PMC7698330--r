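Package: sarfocus
Title: Phased-Array Microwave Hyperthermia Planning on Voxel Breast Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Treatment-planning toolkit for phased-array microwave
    hyperthermia of the female breast. Generates synthetic voxel breast
    phantoms with configurable glandular composition and an embedded
    spherical tumor, computes per-antenna complex electric fields of an
    eight-dipole ring applicator with a finite-difference time-domain
    (FDTD) solver, assembles excitation-independent Hermitian quadratic
    forms for region-averaged specific absorption rate (SAR), optimizes
    antenna powers and phases by maximizing the tumor-to-healthy SAR
    ratio as a generalized Rayleigh quotient, and simulates transient
    tissue temperature with a Pennes bioheat solver that includes a
    nonlinear temperature-dependent tumor perfusion model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
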