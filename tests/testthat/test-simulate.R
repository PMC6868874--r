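# unit-scale config: small genome so each file stays fast
small_cfg <- function(seed = 3L, ...) {
  args <- list(seed = seed, genome_length = 20000L, n_peaks = 8L,
               depth_in_peak = 40, depth_background = 2)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

test_that("simulation is deterministic given the seed", {
  cfg <- small_cfg()
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome$sequences, b$genome$sequences)
  expect_identical(a$truth_cpg, b$truth_cpg)
  ra <- simulate_reads(cfg, a$genome, a$peaks, a$truth_cpg)
  rb <- simulate_reads(cfg, b$genome, b$peaks, b$truth_cpg)
  expect_identical(ra$fragments, rb$fragments)
  # and the on-disk FASTA is byte-identical
  fa <- tempfile(); fb <- tempfile()
  write_fasta(a$genome, fa); write_fasta(b$genome, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("genome honors CpG density, peak packing, and mixture classes", {
  cfg <- small_cfg(seed = 5L)
  g <- simulate_genome(cfg)
  n_cpg <- length(g$genome$cpg_index[[1L]])
  target <- cfg$cpg_rate * cfg$genome_length
  expect_lt(abs(n_cpg - target) / target, 0.2)
  pk <- g$peaks
  expect_identical(nrow(pk), 8L)
  ord <- pk[order(pk$start0), ]
  expect_true(all(ord$start0[-1L] >= ord$end0[-nrow(ord)]))  # non-overlapping
  expect_true(all(pk$end0 <= cfg$genome_length))
  # every truth beta inside its class range
  rng <- list(low = c(0, 0.2), intermediate = c(0.2, 0.8), high = c(0.8, 1))
  for (cl in names(rng)) {
    b <- g$truth_cpg$true_beta[g$truth_cpg$class == cl]
    expect_true(all(b >= rng[[cl]][1L] & b <= rng[[cl]][2L]))
  }
})

test_that("degenerate mixtures and peak counts behave as stated", {
  cfg <- small_cfg(mixture_weights = c(low = 1, intermediate = 0, high = 0))
  g <- simulate_genome(cfg)
  expect_true(all(g$truth_cpg$true_beta < 0.2))
  cfg0 <- small_cfg(n_peaks = 0L)
  g0 <- simulate_genome(cfg0)
  expect_identical(nrow(g0$peaks), 0L)
  rd <- simulate_reads(cfg0, g0$genome, g0$peaks, g0$truth_cpg)
  expect_true(all(rd$fragments$origin == "background"))
  expect_error(simulation_config(mixture_weights = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(small_cfg(n_peaks = 100L, peak_width_mean = 2000,
                         peak_width_sd = 1) |> simulate_genome(),
               "infeasible")
})

test_that("depth_background = 0 puts every fragment in a peak", {
  cfg <- small_cfg(depth_background = 0)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(cfg, g$genome, g$peaks, g$truth_cpg)
  expect_true(all(rd$fragments$origin != "background"))
  in_peak <- mapply(function(ctg, s, e) {
    any(g$peaks$contig == ctg & s < g$peaks$end0 & g$peaks$start0 < e)
  }, rd$fragments$contig, rd$fragments$start0, rd$fragments$end0)
  expect_true(all(in_peak))
})

test_that("noise-free chemistry writes the truth state into the read bases", {
  cfg <- small_cfg(conversion_rate = 1, failure_rate = 0, sequencing_error = 0)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(cfg, g$genome, g$peaks, g$truth_cpg)
  calls <- call_read_methylation(rd$fragments, g$genome)
  expect_identical(sum(calls$state == "AMBIG"), 0L)
  m <- match(paste(calls$query_name, calls$pos0),
             paste(rd$truth_calls$query_name, rd$truth_calls$pos0))
  expect_false(anyNA(m))
  expect_identical(calls$state == "METH", rd$truth_calls$methylated[m])
})

test_that("realized informative coverage over peak CpGs tracks depth_in_peak", {
  cfg <- small_cfg(seed = 9L, conversion_rate = 1, failure_rate = 0,
                   sequencing_error = 0)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(cfg, g$genome, g$peaks, g$truth_cpg)
  sites <- aggregate_sites(call_read_methylation(rd$fragments, g$genome))
  # CpGs strictly interior to peaks (edge CpGs see half the fragment density)
  fs <- filter_sites(sites, transform(g$peaks, start0 = start0 + 100L,
                                      end0 = end0 - 100L), min_coverage = 1L)
  expect_lt(abs(mean(fs$coverage) - cfg$depth_in_peak) / cfg$depth_in_peak,
            0.15)
})

test_that("fragments stay within genome bounds and lengths within [50, 1000]", {
  cfg <- small_cfg(seed = 13L)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(cfg, g$genome, g$peaks, g$truth_cpg)
  f <- rd$fragments
  expect_true(all(f$start0 >= 0L))
  expect_true(all(f$end0 <= contig_lengths(g$genome)[f$contig]))
  len <- f$end0 - f$start0
  expect_true(all(len >= 50L & len <= 1000L))
})

test_that("duplication_rate emits collapsible coordinate duplicates", {
  cfg <- small_cfg(duplication_rate = 0.2)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(cfg, g$genome, g$peaks, g$truth_cpg)
  expect_gt(sum(grepl("dup$", rd$fragments$query_name)), 0L)
  sam <- tempfile(fileext = ".sam")
  write_sam(rd$fragments, sam, g$genome)
  got <- read_alignments(sam)
  key <- paste(got$contig, got$start0, got$end0, got$bisulfite_strand)
  expect_identical(anyDuplicated(key), 0L)
})

test_that("planted motif instances sit at peak summits on both strands", {
  consensus <- "TCGCCACCAGGCGGAGCTA"
  cfg <- small_cfg(seed = 29L, plant_motif = consensus)
  g <- simulate_genome(cfg)
  found <- vapply(seq_len(nrow(g$peaks)), function(i) {
    at <- g$peaks$start0[i] + g$peaks$summit_offset[i]
    s <- genome_subseq(g$genome, g$peaks$contig[i], at, at + nchar(consensus))
    s == consensus || s == revcomp(consensus)
  }, logical(1))
  expect_true(all(found))
  # the scanner recovers the planted instances within peaks
  pwm <- pwm_from_counts(read_jaspar_pfm(
    system.file("extdata", "ctcf_like_synthetic.pfm", package = "tagmeth")))
  thr <- pwm_score_threshold(pwm, pvalue = 1e-4)
  hits <- scan_motifs(g$genome, pwm, thr,
                      regions = g$peaks[, c("contig", "start0", "end0")])
  expect_gte(nrow(hits), nrow(g$peaks))
  offs <- hit_cpg_offsets(hits, g$genome)
  expect_true(all(c(2L, 12L) %in% offs$offset))
})

test_that("simulate_dataset writes the full round-trippable file set", {
  cfg <- small_cfg()
  out <- tempfile("simdir")
  res <- simulate_dataset(cfg, out)
  expect_true(all(file.exists(res$paths)))
  g2 <- read_fasta(res$paths[["ref"]])
  expect_identical(g2$sequences, res$genome$sequences)
  pk2 <- read_narrowpeak(res$paths[["peaks"]])
  expect_identical(pk2[c("contig", "start0", "end0", "name")],
                   res$peaks[c("contig", "start0", "end0", "name")])
  fr <- read_alignments(res$paths[["reads"]])
  expect_gt(nrow(fr), 0L)
})
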