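Package: epigerm
Title: Repressive Epigenetic Marks at REF6 Binding Sites and Gene
    Activation in Germinating Endosperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking combinations of maternal repressive
    epigenetic marks (H3K27me3, H3K9me2 and CHG DNA methylation) at
    REF6-binding sites (the CTCTGYTY motif) to gene activation during seed
    germination and to parent-of-origin expression bias in Arabidopsis
    endosperm.  Provides IUPAC motif scanning over gene bodies with
    per-position cytosine context annotation, bisulfite methylation-call
    rules (two-replicate and pooled), chromatin-state gene stratification
    from mark domains, expression time-course and allelic-ratio statistics,
    Fisher/Wilcoxon enrichment testing with Benjamini-Hochberg correction,
    promoter k-mer overrepresentation, and a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
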