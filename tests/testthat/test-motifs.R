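test_that("PFM to probability matrix arithmetic and validation", {
  m <- matrix(c(8, 0, 0, 0,
                2, 2, 2, 2), nrow = 4, byrow = FALSE,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pwm_from_counts(m, pseudocount = 1)
  expect_equal(pwm$prob[, 1L], c(A = 9, C = 1, G = 1, T = 1) / 12)
  expect_equal(unname(pwm$prob[, 2L]), rep(0.25, 4))
  expect_error(pwm_from_counts(m, pseudocount = 0), "log-odds undefined")
  expect_error(pwm_from_counts(-m), "negative")
  expect_error(pwm_from_counts(m[, 1L, drop = FALSE]), "W >= 2")
  expect_true(all(abs(colSums(pwm$prob) - 1) < 1e-9))
})

test_that("JASPAR PFM text parses with and without row decorations", {
  p <- tempfile(fileext = ".pfm")
  writeLines(c(">MX0001.1 synthetic", "A [ 1 2 3 ]", "C [4 5 6]",
               "G [ 7 8 9 ]", "T [10 11 12]"), p)
  m <- read_jaspar_pfm(p)
  expect_identical(dim(m), c(4L, 3L))
  expect_equal(m["T", ], c(10, 11, 12))
  writeLines(c("1 2", "3 4", "5 6", "7 8"), p)
  expect_equal(read_jaspar_pfm(p)["A", ], c(1, 2))
})

test_that("threshold from the exact score distribution: W = 1 enumeration", {
  # one column heavily favoring A: under uniform background the best base has
  # probability 1/4, so pvalue 0.25 admits exactly that base
  m <- matrix(c(12, 2, 2, 2, 12, 2, 2, 2), nrow = 4)
  rownames(m) <- c("A", "C", "G", "T")
  pwm <- pwm_from_counts(m, pseudocount = 0.5)
  one <- pwm_from_counts(m[, 1L:2L], pseudocount = 0.5)
  thr <- pwm_score_threshold(one, pvalue = 1 / 16)
  # W = 2: only AA (prob 1/16) scores at least the threshold
  enum <- expand.grid(b1 = 1:4, b2 = 1:4)
  scores <- one$log_odds[cbind(enum$b1, 1L)] + one$log_odds[cbind(enum$b2, 2L)]
  expect_identical(sum(scores >= thr), 1L)
  # pvalue 1 admits every sequence
  thr_all <- pwm_score_threshold(one, pvalue = 1)
  expect_true(all(scores >= thr_all))
  expect_error(pwm_score_threshold(one, pvalue = 0), "pvalue")
})

test_that("DP tail matches enumeration over all 4^W sequences (W <= 6)", {
  set.seed(31)
  bin <- 0.01
  for (W in c(2L, 4L, 6L)) {
    pwm <- pwm_from_counts(random_pfm(W), pseudocount = 1)
    enum <- as.matrix(expand.grid(rep(list(1:4), W)))
    scores <- rowSums(matrix(pwm$log_odds[cbind(as.vector(enum),
                                                rep(seq_len(W), each = 4^W))],
                             ncol = W))
    tail_enum <- function(t) mean(scores >= t)
    for (pv in c(0.5, 0.1, 0.01)) {
      thr <- pwm_score_threshold(pwm, pvalue = pv, bin_width = bin)
      slack <- (W + 1L) * bin   # per-column rounding error bound
      # the admitted mass is at most pvalue (up to discretization)
      expect_lte(tail_enum(thr + slack), pv + 1e-12)
      # minimality: one more grid step down would exceed pvalue, unless the
      # threshold already sits at the bottom of the score range
      if (thr > min(scores) + slack) {
        expect_gt(tail_enum(thr - slack - bin), pv)
      }
      # the achieved DP tail agrees with enumeration within the same slack
      dp_tail <- attr(thr, "tail_prob")
      expect_gte(dp_tail, tail_enum(thr + slack) - 1e-12)
      expect_lte(dp_tail, tail_enum(thr - slack) + 1e-12)
    }
  }
})

test_that("scanner agrees exactly with brute-force window enumeration", {
  set.seed(11)
  for (rep in 1:3) {
    W <- sample(3:6, 1L)
    pwm <- pwm_from_counts(random_pfm(W))
    g <- Genome(c(s1 = random_dna(1500)))
    thr <- pwm_score_threshold(pwm, pvalue = 0.01)
    hits <- scan_motifs(g, pwm, thr)
    oracle <- oracle_scan(g$sequences[["s1"]], pwm$log_odds, thr)
    expect_identical(hits$start0, oracle$start0)
    expect_identical(hits$strand, oracle$strand)
    expect_equal(hits$score, oracle$score)
  }
})

test_that("near-consensus ACGT motif finds the planted site on both strands", {
  counts <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  diag(counts) <- 97   # consensus ACGT
  pwm <- pwm_from_counts(counts, pseudocount = 0)
  g <- Genome(c(s1 = "TTTTTACGTTTTT"))
  hits <- scan_motifs(g, pwm, threshold = 4)
  plus <- hits[hits$strand == "+", ]
  expect_identical(plus$start0, 5L)
  # ACGT is its own reverse complement: a minus hit pairs at the same locus
  minus <- hits[hits$strand == "-", ]
  expect_identical(minus$start0, 5L)
  expect_equal(plus$score, minus$score)
})

test_that("windows with non-ACGT bases are skipped; short regions yield none", {
  counts <- matrix(5, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pwm_from_counts(counts)
  g <- Genome(c(s1 = strrep("N", 50)))
  expect_identical(nrow(scan_motifs(g, pwm, threshold = -100)), 0L)
  g2 <- Genome(c(s1 = "ACGTACGTAC"))
  expect_identical(
    nrow(scan_motifs(g2, pwm, -100,
                     regions = data.frame(contig = "s1", start0 = 0L,
                                          end0 = 3L))), 0L)
})

test_that("strand consistency: minus-hit CpGs equal plus-scan of the revcomp", {
  set.seed(23)
  pwm <- pwm_from_counts(random_pfm(5L))
  seq <- random_dna(800)
  g <- Genome(c(s1 = seq))
  g_rc <- Genome(c(s1 = revcomp(seq)))
  thr <- pwm_score_threshold(pwm, pvalue = 0.02)
  hits <- scan_motifs(g, pwm, thr)
  hits_rc <- scan_motifs(g_rc, pwm, thr)
  L <- nchar(seq)
  minus_fwd <- sort(hits$start0[hits$strand == "-"])
  plus_on_rc <- sort(L - 5L - hits_rc$start0[hits_rc$strand == "+"])
  expect_identical(minus_fwd, plus_on_rc)
  # and the recovered forward CpG coordinates agree
  offs <- hit_cpg_offsets(hits, g)
  offs_rc <- hit_cpg_offsets(hits_rc, g_rc)
  cpg_minus <- sort(offs$cpg_pos0[offs$strand == "-"])
  cpg_rc_plus <- sort(L - 2L - offs_rc$cpg_pos0[offs_rc$strand == "+"])
  expect_identical(cpg_minus, cpg_rc_plus)
})

test_that("CpG offsets map hits to forward-strand coordinates", {
  g <- Genome(c(s1 = "AAACGTTAAAAA"))   # CpG C at pos0 3
  hits <- data.frame(contig = "s1", start0 = c(1L, 1L), end0 = c(7L, 7L),
                     strand = c("+", "-"), score = 1,
                     stringsAsFactors = FALSE)
  offs <- hit_cpg_offsets(hits, g)
  plus <- offs[offs$strand == "+", ]
  minus <- offs[offs$strand == "-", ]
  expect_identical(plus$offset, 3L)          # C at motif column 3
  expect_identical(plus$cpg_pos0, 3L)
  expect_identical(minus$cpg_pos0, 3L)       # same forward C
  expect_identical(minus$offset, 6L - 3L)    # W - k_forward
  # hit without a CpG in span reports nothing
  none <- hit_cpg_offsets(data.frame(contig = "s1", start0 = 6L, end0 = 12L,
                                     strand = "+", score = 1), g)
  expect_identical(nrow(none), 0L)
})

test_that("position methylation separates offsets and matches rank sums", {
  ho <- data.frame(hit = 1:6, contig = "s1",
                   start0 = c(10L, 30L, 50L, 70L, 90L, 110L),
                   strand = "+", score = 1,
                   offset = c(2L, 2L, 2L, 12L, 12L, 12L),
                   cpg_pos0 = c(11L, 31L, 51L, 81L, 101L, 121L))
  sites <- make_sites("s1", c(11L, 31L, 51L, 81L, 101L, 121L),
                      c(0L, 0L, 0L, 10L, 10L, 10L), c(10L, 10L, 10L, 0L, 0L,
                                                      0L))
  pm <- position_methylation(ho, sites, offsets = c(2L, 12L))
  expect_equal(unname(pm$medians), c(0, 1))
  expect_equal(pm$test$statistic[["W"]], 0)  # all C2 betas below all C12
  # identical vectors sit at the null mean n1 * n2 / 2
  sites_eq <- make_sites("s1", ho$cpg_pos0, c(1L, 2L, 3L, 1L, 2L, 3L), 7L)
  pm_eq <- position_methylation(ho, sites_eq, offsets = c(2L, 12L))
  expect_equal(pm_eq$test$statistic[["W"]], 4.5)
  # statistic equals the closed-form rank computation
  b1 <- c(0.1, 0.2, 0.3); b2 <- c(0.2, 0.3, 0.4)
  sites_mix <- make_sites("s1", ho$cpg_pos0, as.integer(10 * c(b1, b2)), 0L)
  sites_mix$beta <- c(b1, b2)
  pm_mix <- position_methylation(ho, sites_mix, offsets = c(2L, 12L))
  ranks <- rank(c(b1, b2))
  W_manual <- sum(ranks[1:3]) - 3 * 4 / 2
  expect_equal(pm_mix$test$statistic[["W"]], W_manual)
})

test_that("co-methylation chi-square matches the hand-computed table", {
  # MM=10 MU=10 UM=10 UU=70: marginals 0.2/0.2, E[MM] = 4, chi2 = 14.0625
  states <- c(rep(c("METH", "METH"), 10), rep(c("METH", "UNMETH"), 10),
              rep(c("UNMETH", "METH"), 10), rep(c("UNMETH", "UNMETH"), 70))
  rc <- data.frame(query_name = rep(sprintf("f%03d", 1:100), each = 2L),
                   contig = "s1", pos0 = rep(c(5L, 15L), 100),
                   state = states, stringsAsFactors = FALSE)
  ct <- comethylation_test(rc, cpg_pair = c(5L, 15L))
  expect_identical(unname(ct$counts), c(10L, 10L, 10L, 70L))
  expect_equal(unname(ct$expected[["MM"]]), 4)
  expect_equal(ct$chi_square, 14.0625)
  expect_equal(ct$observed_mm_fraction, 0.10)
  expect_equal(ct$expected_mm_fraction, 0.04)
  # cross-check against the stock Pearson test without continuity correction
  tab <- matrix(c(10, 10, 10, 70), 2)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(ct$chi_square, unname(ref$statistic))
})

test_that("independent counts give chi-square zero; degenerate tables NA", {
  states <- c(rep(c("METH", "METH"), 4), rep(c("METH", "UNMETH"), 16),
              rep(c("UNMETH", "METH"), 16), rep(c("UNMETH", "UNMETH"), 64))
  rc <- data.frame(query_name = rep(sprintf("f%03d", 1:100), each = 2L),
                   contig = "s1", pos0 = rep(c(5L, 15L), 100),
                   state = states, stringsAsFactors = FALSE)
  ct <- comethylation_test(rc, cpg_pair = c(5L, 15L))
  expect_equal(ct$chi_square, 0)
  # all MM: zero marginal variability
  rc_mm <- data.frame(query_name = rep(sprintf("f%d", 1:10), each = 2L),
                      contig = "s1", pos0 = rep(c(5L, 15L), 10),
                      state = "METH", stringsAsFactors = FALSE)
  expect_true(is.na(comethylation_test(rc_mm, c(5L, 15L))$chi_square))
  # AMBIG fragments are excluded from the joint table
  rc$state[1:2] <- "AMBIG"
  ct2 <- comethylation_test(rc, cpg_pair = c(5L, 15L))
  expect_identical(ct2$n, 99L)
})
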