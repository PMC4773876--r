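Package: promarch
Title: Promoter Architecture Analysis for Compact Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising core-promoter architecture in compact
    genomes: gene-density profiling in fixed genomic windows, extraction and
    filtering of core-promoter regions around annotated transcription start
    sites, classification of adjacent gene pairs and promoter directionality
    (unidirectional, bidirectional, putative bidirectional), positional motif
    enrichment from position-weight-matrix and IUPAC consensus scanning,
    promoter-level motif co-occurrence statistics, and the cumulative
    polyadenylation-signal / 5' splice-site frequency profiles that summarise
    the U1-PAS axis of promoter directionality. Includes a synthetic genome
    and annotation simulator with planted ground truth so every pipeline stage
    can be validated against known signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
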