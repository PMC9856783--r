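Package: aptacycle
Title: SELEX Enrichment Analysis, Droplet Digital PCR Quantification and
    Thermofluorimetric Affinity Estimation for Aptamer Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Tools for the computational side of aptamer selection by
    SELEX (Systematic Evolution of Ligands by EXponential enrichment)
    monitored by droplet digital PCR.  Covers trimming of fixed
    primer-binding flanks from deep-sequencing reads, per-cycle sequence
    frequency tables with abundance filtering, sequential clustering of
    sequences into families by Levenshtein edit distance, positive versus
    counter-selection enrichment ranking of candidate aptamers, Poisson
    quantification of droplet digital PCR wells with quality control,
    oligonucleotide concentration and composition bookkeeping, and
    thermofluorimetric melt-curve analysis (melting temperature detection,
    blank subtraction, binding curves and dissociation-constant fits).  A
    seeded synthetic-data generator emulates selection rounds, droplet
    amplitude distributions and two-state melt curves so the whole pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    Biostrings,
    signal,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
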