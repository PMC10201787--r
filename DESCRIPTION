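Package: accessprofiler
Title: Downstream Analysis of ATAC-Seq Tn5 Insertion Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of ATAC-seq data starting from aligned
    paired-end fragments: per-base Tn5 insertion tracks and sliding-window
    density tracks, SPOT (signal portion of tags) scores and organellar
    read fractions, peak merging and two-sample peak-set comparison under a
    minimum-overlap criterion, five-category genomic annotation of peaks
    (exon, intron, 2 kb upstream, 2 kb downstream, intergenic),
    background-normalized accessibility profiles upstream of transcription
    start sites stratified by expression quantile, promoter-window
    accessibility versus expression correlation, and chi-square tests for
    tissue-specific expression enrichment of peak-associated gene classes.
    Includes a synthetic fragment/peak/expression generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
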