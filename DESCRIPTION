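Package: fibrenet
Title: Individual-Based Simulation of Dynamically Crosslinked Fibre Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional individual-based model of extracellular-matrix-like
    fibre networks. Spherocylinder fibre units in a periodic box repel on contact,
    gain and lose crosslinks through Poisson birth-death kinetics, and align at
    their crosslinks, evolving under overdamped dynamics integrated with an
    adaptive explicit Euler scheme. Provides quantifiers of emergent order (local
    alignment indicator, links per fibre, stereographic orientation projection,
    covariance-ellipse semi-major axis, three-state classification, relaxation
    time and logarithmic-law fits), seeded synthetic fixtures with known ground
    truth, replicate and parameter-sweep runners, and CSV/VTK export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
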