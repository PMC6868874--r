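#!/usr/bin/env Rscript
# Simulate the study datasets: a peak-enriched bisulfite tagmentation library
# (the "M-assay": methylation read jointly with accessibility) and a
# flat-coverage whole-genome bisulfite analog over the SAME genome and truth
# methylome, so downstream scripts can compare per-peak methylation across
# the two assays. Writes FASTA/narrowPeak/SAM plus truth TSVs.

suppressMessages(library(tagmeth))

outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# peaks carry one instance of the synthetic TF motif at their summit, the
# way accessibility peaks harbor the occupying factor's site
pfm <- read_jaspar_pfm(system.file("extdata", "ctcf_like_synthetic.pfm",
                                   package = "tagmeth"))
consensus <- paste(rownames(pfm)[apply(pfm, 2L, which.max)], collapse = "")

cfg <- simulation_config(seed = 101L,    # defaults: 200 kb, 50 peaks, 60x/2x
                         plant_motif = consensus)
message("simulating M-assay library (seed ", cfg$seed, ") ...")
ds <- simulate_dataset(cfg, outdir)
message("  ", nrow(ds$fragments), " fragments over ",
        length(ds$genome$cpg_index[[1L]]), " CpGs, ",
        nrow(ds$peaks), " peaks")

# WGBS-like analog: same genome and truth, uniform 30x fragment sampling
cfg_wgbs <- simulation_config(seed = 102L, depth_in_peak = 0,
                              depth_background = 30)
message("simulating WGBS-like analog (uniform coverage) ...")
rd_wgbs <- simulate_reads(cfg_wgbs, ds$genome, ds$peaks, ds$truth_cpg)
write_sam(rd_wgbs$fragments, file.path(outdir, "reads_wgbs_like.sam"),
          ds$genome)
message("  ", nrow(rd_wgbs$fragments), " fragments")

# a second M-assay replicate (new seed, same genome/truth) for QC
cfg_rep2 <- simulation_config(seed = 103L)
rd_rep2 <- simulate_reads(cfg_rep2, ds$genome, ds$peaks, ds$truth_cpg)
write_sam(rd_rep2$fragments, file.path(outdir, "reads_rep2.sam"), ds$genome)
message("  replicate 2: ", nrow(rd_rep2$fragments), " fragments")

message("wrote ", paste(basename(c(ds$paths, "reads_wgbs_like.sam",
                                   "reads_rep2.sam")), collapse = ", "),
        " under ", outdir)
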