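Package: ancientdel
Title: Ancient Deletion Polymorphisms and Signatures of Balancing Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study deletion polymorphisms that predate the split of
    anatomically modern humans from Neanderthals and Denisovans. Provides a
    coalescent engine for the neutral expectation of derived-allele sharing
    with archaic genomes (including ancestral population structure with
    migration), read-depth genotyping of deletions in archaic genomes via
    modified Z-scores, linkage-disequilibrium-based classification of shared
    deletions into recurrent, introgressed and ancient categories, an
    allele-frequency stability statistic from genealogical lineage counts,
    permutation enrichment tests for functional annotation and length, and
    forward/structured-coalescent simulators of overdominance together with
    the classical summary-statistic panel. A seeded synthetic-data generator
    with planted ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
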