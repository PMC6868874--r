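Package: tagmeth
Title: Joint DNA Methylation and Chromatin Accessibility Analysis from
    Bisulfite Tagmentation Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of assays that read CpG methylation and
    chromatin accessibility or transcription-factor occupancy from the same
    DNA molecules (bisulfite-converted ATAC-seq or ChIPmentation libraries).
    Provides strand-aware methylation calling from aligned directional
    bisulfite fragments, aggregation to CpG sites with peak and coverage
    filters, per-peak methylation summaries and cross-assay quadrant
    classification, a methylation-by-coverage CpG grouping with a
    normal-approximation cluster-membership probability, position weight
    matrix scanning with exact score-distribution p-value thresholds,
    motif-position methylation comparisons, and a per-fragment CpG
    co-methylation chi-square test. A synthetic bisulfite-read simulator
    generates peak-enriched directional paired-end fragments over a toy
    genome with a mixture methylome for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
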