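Package: oritools
Title: Replication-Origin Colocalization, GC-Matched Motif Nulls, and
    DNA-Combing Statistics
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for analysing the relationship between protein-binding
    ChIP-seq peaks and replication-initiation (nascent-strand) peaks.
    Provides proximity classification and colocalization fractions,
    distance-distribution profiles around origin centres, stratification of
    origins by binding status, selection of compact high-scoring isolated
    peak subsets for motif discovery, a length- and GC-matched randomized
    genomic null for motif-containment enrichment, IUPAC motif scanning on
    both strands, DNA-combing (fibre) replication statistics (fork speed,
    inter-origin distance, fork asymmetry, Mann-Whitney comparisons), a
    coexpression z-score screen, and synthetic-data generators with known
    ground truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
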