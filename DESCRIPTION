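Package: ripscape
Title: Intron-Aware RIP-Seq Quantification and Poly(A) Tail Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for gene-level analysis of RNA immunoprecipitation
    sequencing (RIP-seq) and nanopore direct-RNA data in the presence of
    incompletely spliced transcripts. Provides annotation sanitization
    (supplemental gene merging, readthrough-transcript removal, and removal
    of genomic regions claimed by two or more genes), exon/intron-aware
    read assignment with a minimum-overlap rule, combined exonic+intronic
    TPM, per-gene intron/exon splicing ratios, detection of genes
    contaminated by upstream readthrough transcription, enrichment
    classification of differential-abundance tables with a histone-gene
    background filter, long-read alignment filtering with per-read intron
    retention calls, per-gene poly(A) tail-length statistics, and a
    deterministic synthetic-data generator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, RNASeq, Annotation, Coverage, LongRead
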