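Package: chromassoc
Title: Linking Chromatin Accessibility to Transcription by Distance, Overlap and Fragment Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating regulatory-element accessibility to gene
    expression in epigenomic studies of B-cell development. Implements a
    merged differential statistic (log2 fold-change times -log10 FDR),
    distance-binned peak-to-TSS association with quantile-quantile and
    differential-histogram summaries, exclusive multi-set Venn partitioning
    of peak sets, enhancer classification by histone-mark co-occurrence with
    promoter/intragenic/intergenic annotation, and ATAC-seq fragmentomics
    (Tn5 insertion-offset correction, nucleosome fragment-size binning,
    normalized coverage and cut-site tracks, binned footprint profiles).
    Ships seeded synthetic-data generators that plant known structure so the
    full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
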