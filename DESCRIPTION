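Package: rhodoquant
Title: Identification, Classification and Quantification of Proteorhodopsin
    Genes in Marine Meta-Omic and qPCR Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to identify proteorhodopsin (PR) proteins in predicted
    metagenome gene sets, classify their proton-pumping triad (D97/T101/E108)
    and spectral tuning residue (position 105, green vs blue), cluster them
    into protein OTUs by greedy identity clustering, and quantify
    PR-bearing bacteria from metagenomes (single-copy housekeeping gene
    normalization), metatranscriptomes (housekeeping-normalized relative
    expression and blue/green transcript partition) and qPCR runs
    (standard-curve absolute quantification with 16S copy-number
    correction). Includes an exact affine-gap pairwise protein aligner and
    a ground-truthed synthetic community generator for validating every
    estimator by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
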