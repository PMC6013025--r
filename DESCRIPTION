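Package: biofilmr
Title: Individual-Based Simulation of Antibiotic Response in Two-Lineage Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spatially explicit individual-based model of a surface-attached
    microbial community formed by an antibiotic-resistant (R) and a susceptible
    (S) lineage. Cells are disks on a 2D domain that grow by Monod kinetics on
    solutes whose concentration fields are held at pseudo-steady state by a
    nonlinear reaction-diffusion solver, divide, and shove each other apart.
    Four metabolic media place the pair on the conflict-mutualism continuum
    (interference competition, exploitation competition, non cross-feeding,
    cross-feeding); a bacteriostatic antibiotic, costly resistance, and
    growth-coupled detoxification can be layered on top. Includes inoculation
    generators, a spatial segregation index, ecological outcome statistics
    (competitive release, mutualistic suppression, cross-species phenotypic
    resistance), and pre-configured experiment suites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
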