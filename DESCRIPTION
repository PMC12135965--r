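Package: whixscan
Title: Profile-Based Discovery and Classification of WHIX-Domain T6SS Effectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for defining and characterising a class of
    type VI secretion system (T6SS) cargo effectors that share a bipartite
    secretion domain marked by a conserved WHxxxH motif. Provides
    position-specific scoring matrix (PSSM) construction with iterative
    profile enrichment and empirically calibrated E-values, a
    position-specific Smith-Waterman scanner, effector subclassification by
    N-terminal extension length, genomic-neighborhood extraction with
    contig-end and duplicate-locus filtering, a T6SS core-component census,
    all-vs-all clustering of toxin extension sequences, and two-group
    label-free quantification (LFQ) secretome enrichment. A synthetic-data
    module generates protein databases, genome feature tables and LFQ tables
    with known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
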