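Package: sbsfold
Title: Strings-and-Binders Polymer Modelling of Chromatin Folding
Version: 0.1.0
Authors@R: person("sbsfold", "developers", role = c("aut", "cre"),
    email = "maintainer@sbsfold.invalid")
Description: Simulation and inference toolkit for the Strings & Binders (SBS)
    polymer model of chromatin. Runs Langevin dynamics of a bead-spring chain
    interacting with diffusing molecular binders across the coil/theta/globule
    phase diagram, computes contact-probability scaling, contact matrices,
    structure factors and many-body contact statistics, fits contact-decay
    curves as mixtures of pure thermodynamic states, infers multi-colour
    binding-site profiles that reproduce a target contact matrix by
    simulated-annealing Monte Carlo, and predicts contact maps of structural
    variants (deletions) with no refitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse,
    igraph,
    GenomicRanges,
    IRanges,
    rtracklayer,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
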