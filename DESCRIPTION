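Package: sacsim
Title: Bistable Spindle Assembly Checkpoint Model and Single-Cell Adaptation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and exact stochastic simulation of a bistable model of
    the budding-yeast spindle assembly checkpoint (mitotic checkpoint) with an
    Mps1-mediated positive feedback loop and transcriptional bursting. Provides
    bifurcation analysis and saddle-node location in the number of unattached
    kinetochores, first-passage ensembles for checkpoint adaptation (mitotic
    slippage) under persistent arrest and after drug washout, mutant transforms
    for reduced APC/C-Cdc20 association (APC-A) and Mad2 overexpression
    (GAL1-MAD2), single-cell fluorescence trace classification (Mad2
    localization index, Clb2 degradation rules), a ground-truth synthetic-data
    generator for time-lapse readouts, and a chromosome missegregation
    predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    deSolve,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
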