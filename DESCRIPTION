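Package: lncScout
Title: Identification, Classification and Functional Profiling of Long
    Non-Coding RNAs from Assembled Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide long non-coding RNA
    (lncRNA) analysis from an assembled transcriptome: a filter cascade
    identifying lncRNAs (multi-exon structure, strand, exonic overlap with
    coding genes, longest open reading frame, coding-potential evidence,
    read support), positional classification against coding genes
    (intergenic, antisense, intronic, other), comparative characterization
    (length, exon/intron size, GC content, expression) with TMM/FPKM
    normalization, a max-fraction tissue-specificity score, and
    guilt-by-association function inference via Pearson co-expression and
    hypergeometric term enrichment with Benjamini-Hochberg correction. A
    seeded synthetic-data generator plants ground truth (coding ORFs,
    frame-broken lncRNAs, positional classes, decoys, tissue-specific and
    co-expressed blocks, enriched terms) so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
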