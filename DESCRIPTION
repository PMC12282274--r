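Package: rbptools
Title: Classification, Quantification and Binding Profiling of Phage
    Receptor-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the receptor-binding proteins (RBPs) of
    lactococcal Skunavirus phages. Extracts the variable C-terminal head
    domain from RBP amino-acid sequences, builds all-against-all pairwise
    identity/coverage matrices by global alignment, assigns two-tier
    group/subgroup labels with explicit identity and coverage thresholds,
    draws neighbor-joining trees of head domains, filters read-to-reference
    alignments and computes relative abundance and RPKM, and normalizes
    fluorescence binding-assay plates into relative binding-affinity
    scores. Includes synthetic-data generators with ground truth so every
    stage can be verified without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rcpp,
    Rsamtools,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
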