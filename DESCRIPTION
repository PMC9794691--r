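Package: persisterlab
Title: Drug-Tolerant Persister Screening and Multi-Omics Integration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering therapeutic vulnerabilities in
    osimertinib drug-tolerant persister (DTP) cells. Implements
    confluence-based combination drug-screen scoring (AUC, combination and
    monotherapy activity, hit calling across cell-line panels), consensus
    ATAC-seq peak construction from summit calls, empirical-Bayes moderated
    differential analysis of RNA and chromatin count matrices, cross-cell-line
    Fisher meta-analysis, RNA-ATAC concordance classification, PWM motif
    scanning and hypergeometric enrichment, signed-network causal
    upstream-regulator inference, and seed-deterministic synthetic-data
    generators (growth curves with persister dynamics, negative-binomial
    counts with planted effects, peaks with planted motifs, signed regulator
    networks) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
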