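#!/usr/bin/env Rscript
# CpG grouping by methylation and coverage: the four-group classification of
# filtered peak CpGs (low/intermediate/high methylation crossed with low/high
# coverage), and the normal-approximation probability that each CpG's beta
# lies within its group's methylation bounds.

suppressMessages(library(tagmeth))

methdir <- "results/methylation"
outdir <- "results/groups"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

filtered <- read.table(file.path(methdir, "matac_filtered.tsv"),
                       header = TRUE, sep = "\t")
gs <- group_summary(filtered, grouping_thresholds())
write.table(gs$sites, file.path(outdir, "groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gs$summary, file.path(outdir, "group_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("group sizes:")
for (i in seq_len(nrow(gs$summary))) {
  message(sprintf("  %-10s %6d sites  median beta %s  median coverage %s",
                  gs$summary$label[i], gs$summary$count[i],
                  format(gs$summary$median_beta[i], digits = 3),
                  format(gs$summary$median_coverage[i], digits = 3)))
}

grouped <- gs$sites[gs$sites$label %in% c("G1", "G2", "G3", "G4"), ]
high_conf <- mean(grouped$membership_probability > 0.72)
message(sprintf(
  "%.1f%% of grouped CpGs have membership probability above 0.72 (n = %d)",
  100 * high_conf, nrow(grouped)))
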