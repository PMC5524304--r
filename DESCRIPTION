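Package: ohnocne
Title: Conserved Non-Coding Elements and Coding-Sequence Evolution Around
    Whole-Genome-Duplication Paralogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the fate of gene duplicates produced by the
    teleost-specific whole-genome duplication (WGD) and of the conserved
    non-coding elements (CNEs) surrounding them. Implements a seed-and-extend
    scanner that calls CNEs from reference-anchored multi-species alignments,
    a local aligner with explicit match/mismatch/gap scoring for fish-specific
    pairwise CNE discovery, partition statistics describing the asymmetric
    retention of ancestral CNEs between WGD paralogs a and b, branch-partitioned
    Goldman-Yang codon models (one, two or three dN/dS classes) with
    likelihood-ratio tests, duplicate-retention landscape summaries, and
    delta-delta-Ct relative expression quantification. A synthetic-data module
    generates every input with controlled ground truth so the whole pipeline is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
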