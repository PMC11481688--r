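Package: singleEV
Title: Single Extracellular Vesicle Phenotyping from dSTORM Localizations
    and Nano-Flow Traces
Version: 0.1.0
Authors@R:
    person("EV", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing single extracellular vesicles (EVs)
    labelled against two tetraspanin markers (CD81/AF647 and CD9/AF488).
    Groups repeated single-molecule blinking events from two-channel dSTORM
    localization tables into molecules, detects particle clusters, computes
    per-cluster shape and density descriptors, and calls single-positive and
    double-positive phenotypes.  Two independent false-positive-correction
    procedures remove antibody aggregates masquerading as single-positive
    EVs: a two-component lognormal decomposition of radius-of-gyration
    histograms, and feature-based classification (random forest, logistic
    regression, linear SVM).  A companion set of functions detects bursts in
    nano-flow cytometry intensity traces, calls event phenotypes, and
    calibrates side-scatter intensity against size beads.  A synthetic-data
    module generates labelled localization tables and flow traces so every
    stage of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
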