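Package: lineagetx
Title: Cell-Lineage Transcriptome Analysis for Early Plant Embryogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of cell-type resolved RNA-seq for the
    asymmetric zygote division in plant embryogenesis: FPKM
    normalization, negative-binomial differential expression between
    apical and basal cell lineages, lineage-maintained gene calling,
    transcript-fate classification (inherited, de novo, selectively
    deleted), sample-level correlation/clustering/PCA, hypergeometric
    enrichment with Benjamini-Hochberg adjustment, promoter-motif and
    coexpression based transcription-factor network inference, consensus
    long noncoding RNA calling, and alternative-splicing event
    classification. Includes a fully parameterised synthetic-data
    generator with planted ground truth so the whole pipeline can be
    exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust
Config/testthat/edition: 3
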