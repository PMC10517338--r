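Package: utrcensus
Title: Curation and Benchmarking of Pathogenic UTR Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating pathogenic and likely pathogenic variants in
    5' and 3' untranslated regions (UTRs) and benchmarking variant effect
    predictors against them. Provides transcript-context confidence scoring
    of UTR variants across overlapping transcripts, APPRIS/MANE-aware
    inclusion rules, population-frequency and variant-type filters, a curated
    census of 94 P/LP UTR variants stratified by molecular mechanism,
    assembly of benchmark sets with putative-benign variants, three
    variant-effect aggregation schemes (transcription-window, mRNA-stability
    ensemble, ribosome-load fold change), PhyloP conservation annotation, and
    a stratified statistical evaluation layer (rank-sum tests, ROC/AUC,
    threshold selection). A synthetic-data generator produces every input
    format so the whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
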