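Package: sacph
Title: pH-Regulated Soluble Adenylyl Cyclase: Genotyping, Kinetics, and
    Sperm-Activation Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for soluble adenylyl cyclase (sAC) orthologs
    that are controlled by intracellular pH rather than bicarbonate or
    calcium. Provides reference-anchored pairwise protein alignment and
    bicarbonate-binding-site genotyping (the K95/R176 polymorphism of the
    human enzyme), cAMP assay-plate reduction to enzymatic activities and
    turnover numbers with rank-based statistics and false-discovery-rate
    control, a flagellar cAMP budget and a deterministic model of the
    spawning cascade (membrane potential, intracellular pH, cAMP, motility),
    dark-field sperm-movie motility scoring, and seeded synthetic-data
    generators that emulate each of these inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    EBImage,
    ape,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
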