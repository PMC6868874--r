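#!/usr/bin/env Rscript
# Peak-level integration: mean CpG methylation per peak in the tagmentation
# assay versus the WGBS-like analog, the 2x2 quadrant classification of
# shared peaks, and the library QC statistics (peak-set Jaccard, binned
# read-count correlation between replicates, fragment length histogram).

suppressMessages(library(tagmeth))

simdir <- "results/sim"
methdir <- "results/methylation"
outdir <- "results/peaks"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta(file.path(simdir, "ref.fa"))
peaks <- read_narrowpeak(file.path(simdir, "peaks.narrowPeak"))
fa <- read.table(file.path(methdir, "matac_filtered.tsv"), header = TRUE,
                 sep = "\t")
fb <- read.table(file.path(methdir, "wgbs_like_filtered.tsv"), header = TRUE,
                 sep = "\t")

pm_a <- peak_mean_methylation(peaks, fa)
pm_b <- peak_mean_methylation(peaks, fb)
write.table(pm_a, file.path(outdir, "peak_methylation_matac.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pm_b, file.path(outdir, "peak_methylation_wgbs_like.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

shared <- intersect(pm_a$name, pm_b$name)
r <- cor(pm_a$mean_beta[match(shared, pm_a$name)],
         pm_b$mean_beta[match(shared, pm_b$name)])
message(sprintf(
  "per-peak mean methylation, %d shared peaks: Pearson r = %.3f",
  length(shared), r))

q <- quadrant_counts(pm_a, pm_b, threshold = 0.5)
write.table(q$per_peak, file.path(outdir, "quadrants.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("quadrant counts (M-assay x axis, WGBS-like y axis): ",
        paste(names(q$counts), q$counts, sep = "=", collapse = ", "))

# QC block
frags1 <- read_alignments(file.path(simdir, "reads.sam"))
frags2 <- read_alignments(file.path(simdir, "reads_rep2.sam"))
qc <- c(
  jaccard_self = interval_jaccard(peaks, peaks),
  replicate_binned_pearson = binned_pearson(frags1, frags2, genome,
                                            bin_size = 5000L),
  fragment_length_mean = fragment_length_histogram(frags1)$mean,
  fragment_length_median = fragment_length_histogram(frags1)$median)
write.table(data.frame(metric = names(qc), value = unname(qc)),
            file.path(outdir, "qc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf(
  "QC: replicate binned-count r = %.3f; fragment length mean %.0f, median %.0f",
  qc[["replicate_binned_pearson"]], qc[["fragment_length_mean"]],
  qc[["fragment_length_median"]]))
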