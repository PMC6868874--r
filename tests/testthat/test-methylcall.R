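# reference "TACGT": CpG with C at pos0 2 and G at pos0 3

test_that("OT calls read the C position: C = METH, T = UNMETH, else AMBIG", {
  g <- tiny_genome("TACGT")
  states <- vapply(c("C", "T", "A"), function(b) {
    f <- make_fragment(seq1 = paste0("TA", b, "GT"))
    call_read_methylation(f, g)$state
  }, character(1))
  expect_identical(unname(states), c("METH", "UNMETH", "AMBIG"))
  expect_identical(call_read_methylation(make_fragment(), g)$pos0, 2L)
})

test_that("OB calls read the paired G: G = METH, A = UNMETH, else AMBIG", {
  g <- tiny_genome("TACGT")
  states <- vapply(c("G", "A", "C"), function(b) {
    f <- make_fragment(strand = "OB", seq1 = paste0("TAC", b, "T"))
    call_read_methylation(f, g)$state
  }, character(1))
  expect_identical(unname(states), c("METH", "UNMETH", "AMBIG"))
  # the OB call is addressed at the forward-strand C position
  f <- make_fragment(strand = "OB", seq1 = "TACAT")
  expect_identical(call_read_methylation(f, g)$pos0, 2L)
})

test_that("base quality below the threshold forces AMBIG", {
  g <- tiny_genome("TACGT")
  f <- make_fragment(qual1 = "II3II", qual2 = "II3II")  # '3' = Q18 at the C
  expect_identical(call_read_methylation(f, g, min_base_quality = 20L)$state,
                   "AMBIG")
  expect_identical(call_read_methylation(f, g, min_base_quality = 15L)$state,
                   "METH")
})

test_that("mate overlap resolves by base quality, ties to read 1", {
  g <- tiny_genome("TACGT")
  # read1 says METH at Q30, read2 says UNMETH at Q40: read2 wins
  f <- make_fragment(seq1 = "TACGT", qual1 = "II?II",
                     seq2 = "TATGT", qual2 = "IIIII")
  expect_identical(call_read_methylation(f, g)$state, "UNMETH")
  # equal quality: read1 wins
  f <- make_fragment(seq1 = "TACGT", qual1 = "IIIII",
                     seq2 = "TATGT", qual2 = "IIIII")
  expect_identical(call_read_methylation(f, g)$state, "METH")
})

test_that("a CpG in the fragment span but under neither mate yields no call", {
  g <- tiny_genome(paste0(strrep("A", 60), "CG", strrep("A", 60), "CG",
                          strrep("A", 56)))  # CpGs at 60 and 122
  f <- make_fragment(start0 = 0L, end0 = 180L,
                     seq1 = strrep("A", 50), pos1 = 0L,
                     seq2 = paste0(strrep("A", 42), "CG", strrep("A", 6)),
                     pos2 = 80L)
  calls <- call_read_methylation(f, g)
  expect_identical(calls$pos0, 122L)   # CpG at 60 falls in the mate gap
})

test_that("caller errors on a contig missing from the genome", {
  g <- tiny_genome("TACGT")
  f <- make_fragment(contig = "cX")
  expect_error(call_read_methylation(f, g), "absent from genome")
})

test_that("aggregation pools counts and drops AMBIG from both counts", {
  calls <- data.frame(
    query_name = sprintf("f%d", 1:4), contig = "c1", pos0 = 2L,
    strand = "OT", state = c("METH", "METH", "UNMETH", "AMBIG"),
    stringsAsFactors = FALSE)
  s <- aggregate_sites(calls)
  expect_identical(s$count_meth, 2L)
  expect_identical(s$count_unmeth, 1L)
  expect_identical(s$coverage, 3L)
  expect_equal(s$beta, 2 / 3)
  # AMBIG-only site is omitted
  only_ambig <- calls[4L, ]
  expect_identical(nrow(aggregate_sites(only_ambig)), 0L)
})

test_that("destranding pools counts, never averages betas", {
  calls <- data.frame(
    query_name = sprintf("f%d", 1:4), contig = "c1", pos0 = 2L,
    strand = c("OT", "OT", "OB", "OB"),
    state = c("METH", "METH", "METH", "UNMETH"),
    stringsAsFactors = FALSE)
  merged <- aggregate_sites(calls, merge_strands = TRUE)
  expect_identical(merged$count_meth, 3L)
  expect_identical(merged$count_unmeth, 1L)
  expect_equal(merged$beta, 0.75)   # count-pooled, not mean(1, 0.5)
  stranded <- aggregate_sites(calls, merge_strands = FALSE)
  expect_identical(nrow(stranded), 2L)
  expect_true(all(merged$coverage >= stranded$coverage))
})

test_that("conservation: meth + unmeth + ambig = calls per CpG", {
  cfg <- simulation_config(seed = 21L, genome_length = 10000L, n_peaks = 4L,
                           depth_in_peak = 30)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(cfg, g$genome, g$peaks, g$truth_cpg)
  calls <- call_read_methylation(rd$fragments, g$genome)
  sites <- aggregate_sites(calls)
  per_cpg <- table(paste(calls$contig, calls$pos0))
  ambig <- table(paste(calls$contig, calls$pos0)[calls$state == "AMBIG"])
  key <- paste(sites$contig, sites$pos0)
  n_amb <- ifelse(key %in% names(ambig), ambig[key], 0L)
  expect_equal(unname(sites$coverage + n_amb), unname(as.integer(per_cpg[key])))
})

test_that("filter_sites applies coverage and half-open peak containment", {
  # 20-site fixture around one peak [100, 200)
  pos <- c(50L, 99L, 100L, 150L, 199L, 200L, 201L, 300L,
           105L, 110L, 115L, 120L, 125L, 130L, 135L, 140L, 145L, 155L, 160L,
           165L)
  cov_m <- c(rep(3L, 8L), 5L, 4L, 6L, 0L, 10L, 2L, 5L, 5L, 5L, 7L, 8L, 9L)
  sites <- make_sites("c1", pos, cov_m, 0L)
  peaks <- make_peaks("c1", 100L, 200L, "pk")
  kept <- filter_sites(sites, peaks, min_coverage = 5L)
  # inside [100, 200) means pos in {100..199}; coverage >= 5
  expect_setequal(kept$pos0, c(105L, 115L, 125L, 135L, 140L, 145L, 155L,
                               160L, 165L))
  expect_false(100L %in% kept$pos0[kept$coverage < 5L])
  expect_false(200L %in% kept$pos0)   # pos0 == end is outside (half-open)
  expect_false(99L %in% kept$pos0)
  expect_true(all(kept$peaks == "pk"))
  # boundary: coverage 4 dropped, 5 kept
  expect_false(110L %in% kept$pos0)
  expect_true(105L %in% kept$pos0)
  # a heavily covered site outside all peaks is dropped
  far <- make_sites("c1", 300L, 50L, 0L)
  expect_identical(nrow(filter_sites(far, peaks)), 0L)
  # empty peak list warns and returns empty
  expect_warning(none <- filter_sites(sites, peaks[0L, ]), "empty peak list")
  expect_identical(nrow(none), 0L)
})

test_that("sites at boundary pos0 = peak start are kept", {
  sites <- make_sites("c1", 100L, 10L, 0L)
  peaks <- make_peaks("c1", 100L, 200L)
  expect_identical(nrow(filter_sites(sites, peaks)), 1L)
})

test_that("a site inside two overlapping peaks is annotated with both", {
  sites <- make_sites("c1", 150L, 10L, 0L)
  peaks <- make_peaks("c1", c(100L, 140L), c(200L, 260L))
  kept <- filter_sites(sites, peaks)
  expect_identical(kept$peaks, "p1,p2")
})
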