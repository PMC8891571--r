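Package: tumorcpm
Title: Multiscale Cellular Potts Simulation of Tumour Growth, Angiogenesis
    and Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-dimensional multiscale simulator of solid tumour growth
    coupling a Boolean signal-transduction network that decides each cell's
    phenotype (growth, proliferation, apoptosis, migration), a cellular Potts
    model for cell mechanics on a voxel lattice, and explicit reaction-
    diffusion fields for nutrient, VEGF and a cytotoxic drug. Includes
    tumour-induced angiogenesis via VEGF-driven endothelial activation with
    VE-cadherin contact inhibition, chemotherapy scheduling (dose, cycle
    length, initiation day, MTD versus metronomic regimens), targeted therapy
    modelled as receptor blockade, and treatment metrics such as the fraction
    of killed cells. Ships synthetic scenario generators, attractor and
    input-output analysis of the signalling network, and a command-line
    interface.
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
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
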