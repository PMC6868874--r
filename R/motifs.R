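#' Read a JASPAR-style PFM text file
#'
#' Accepts the JASPAR text dialect: an optional `>` header line followed by
#' four rows of whitespace-separated counts in A, C, G, T order, with or
#' without the `A [ ... ]` row decorations.
#'
#' @param path PFM file
#' @return 4 x W numeric count matrix with rownames A, C, G, T
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^>", lines)]
  if (length(lines) != 4L) stop("expected 4 count rows in ", path)
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]?\\s*\\[", "", l)
    l <- gsub("\\]\\s*$", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  w <- unique(lengths(rows))
  if (length(w) != 1L) stop("ragged count rows in ", path)
  m <- do.call(rbind, rows)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' Build a position probability matrix from counts
#'
#' Column-wise `(count + pseudocount) / (colsum + 4 * pseudocount)`. The
#' background is stored alongside; every entry must be positive after the
#' pseudocount so log-odds are defined.
#'
#' @param count_matrix 4 x W nonnegative count matrix (rows A, C, G, T)
#' @param pseudocount additive smoothing per cell
#' @param background length-4 base frequencies (default uniform)
#' @return a `MotifMatrix`: list with `prob` (4 x W), `width`, `background`,
#'   `pseudocount`, and `log_odds` (base-2 log odds, 4 x W)
#' @export
pwm_from_counts <- function(count_matrix, pseudocount = 1,
                            background = rep(0.25, 4)) {
  m <- as.matrix(count_matrix)
  if (nrow(m) != 4L || ncol(m) < 2L) stop("count matrix must be 4 x W, W >= 2")
  if (any(m < 0)) stop("negative counts")
  if (any(colSums(m) + 4 * pseudocount <= 0) ||
      any(m + pseudocount <= 0)) {
    stop("pseudocount leaves zero entries: log-odds undefined")
  }
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-9)
  prob <- sweep(m + pseudocount, 2L, colSums(m) + 4 * pseudocount, "/")
  rownames(prob) <- c("A", "C", "G", "T")
  background <- stats::setNames(as.numeric(background), c("A", "C", "G", "T"))
  structure(list(prob = prob, width = ncol(prob), background = background,
                 pseudocount = pseudocount,
                 log_odds = log2(prob / background)),
            class = "MotifMatrix")
}

#' @export
print.MotifMatrix <- function(x, ...) {
  cat(sprintf("MotifMatrix: width %d, pseudocount %g\n", x$width,
              x$pseudocount))
  print(round(x$prob, 3))
  invisible(x)
}

#' Score threshold from the exact score distribution
#'
#' Computes the distribution of the motif log-odds score under the background
#' model by position-wise convolution on a discretized score grid
#' (`bin_width` bits per bin), then returns the smallest grid score whose
#' upper-tail probability is at most `pvalue`. Matching windows at or above
#' the threshold therefore have background probability <= `pvalue` up to
#' discretization.
#'
#' @param matrix a [pwm_from_counts()] MotifMatrix
#' @param pvalue target tail probability, in (0, 1]; 1 admits every window
#' @param bin_width score grid resolution in bits
#' @return the score threshold (bits), with the achieved tail probability as
#'   attribute `tail_prob`
#' @export
pwm_score_threshold <- function(matrix, pvalue = 1e-4, bin_width = 0.01) {
  stopifnot(inherits(matrix, "MotifMatrix"))
  if (pvalue <= 0 || pvalue > 1) stop("pvalue must be in (0, 1]")
  lo_bins <- round(matrix$log_odds / bin_width)
  offset <- sum(apply(lo_bins, 2L, min))
  span <- sum(apply(lo_bins, 2L, max)) - offset + 1L
  dist <- numeric(span)          # dist[k] = P(binned score == offset + k - 1)
  dist[1L] <- 1
  bg <- matrix$background
  for (j in seq_len(matrix$width)) {
    cmin <- min(lo_bins[, j])
    new <- numeric(span)
    for (base in 1:4) {
      shift <- lo_bins[base, j] - cmin
      if (bg[base] == 0) next
      idx <- seq_len(span - shift)
      new[idx + shift] <- new[idx + shift] + bg[base] * dist[idx]
    }
    dist <- new
  }
  scores <- (offset + seq_len(span) - 1L) * bin_width
  tail <- rev(cumsum(rev(dist)))
  ok <- which(tail <= pvalue + 1e-12)
  if (length(ok) == 0L) {
    # even the best score is more probable than pvalue: threshold above max
    thr <- scores[span] + bin_width
    attr(thr, "tail_prob") <- 0
    return(thr)
  }
  thr <- scores[min(ok)]
  attr(thr, "tail_prob") <- tail[min(ok)]
  thr
}

# integer-encode a sequence: A=1 C=2 G=3 T=4, other = NA
encode_seq <- function(s) {
  v <- utf8ToInt(toupper(s))
  code <- rep(NA_integer_, 128L)
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  code[v]
}

# score every window of an encoded sequence against a 4 x W log-odds matrix;
# windows containing non-ACGT bases come back NA
score_windows <- function(enc, log_odds) {
  W <- ncol(log_odds)
  n <- length(enc) - W + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  na <- logical(n)
  for (j in seq_len(W)) {
    b <- enc[j:(j + n - 1L)]
    bad <- is.na(b)
    na <- na | bad
    b[bad] <- 1L
    sc <- sc + log_odds[cbind(b, j)]
  }
  sc[na] <- NA_real_
  sc
}

#' Scan a genome for motif occurrences
#'
#' Slides the motif over both strands of the requested regions and keeps
#' windows whose base-2 log-odds score is at or above `threshold`. Hits are
#' reported in forward-strand coordinates (0-based half-open span of width
#' W); minus-strand hits are windows whose reverse complement matches the
#' motif. Windows containing non-ACGT bases are skipped. Regions shorter
#' than the motif yield no hits.
#'
#' @param genome a [Genome()]
#' @param matrix a [pwm_from_counts()] MotifMatrix
#' @param threshold minimum score in bits (e.g. from
#'   [pwm_score_threshold()])
#' @param regions optional data.frame (`contig`, `start0`, `end0`) limiting
#'   the scan; default scans every contig fully
#' @return data.frame of hits: `contig`, `start0`, `end0`, `strand`, `score`
#' @export
scan_motifs <- function(genome, matrix, threshold, regions = NULL) {
  stopifnot(inherits(genome, "Genome"), inherits(matrix, "MotifMatrix"))
  if (is.null(regions)) {
    lens <- contig_lengths(genome)
    regions <- data.frame(contig = names(lens), start0 = 0L,
                          end0 = unname(lens), stringsAsFactors = FALSE)
  }
  W <- matrix$width
  lo <- matrix$log_odds
  lo_rc <- lo[4:1, W:1, drop = FALSE]   # reverse complement strand
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ctg <- regions$contig[i]
    s0 <- regions$start0[i]
    e0 <- regions$end0[i]
    if (e0 - s0 < W) next
    enc <- encode_seq(genome_subseq(genome, ctg, s0, e0))
    fwd <- score_windows(enc, lo)
    rev <- score_windows(enc, lo_rc)
    keep_f <- which(!is.na(fwd) & fwd >= threshold)
    keep_r <- which(!is.na(rev) & rev >= threshold)
    if (length(keep_f) + length(keep_r) == 0L) next
    out[[i]] <- data.frame(
      contig = ctg,
      start0 = s0 + c(keep_f, keep_r) - 1L,
      end0 = s0 + c(keep_f, keep_r) - 1L + W,
      strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
      score = c(fwd[keep_f], rev[keep_r]),
      stringsAsFactors = FALSE)
  }
  hits <- rbind_rows(out)
  if (is.null(hits)) {
    hits <- data.frame(contig = character(0), start0 = integer(0),
                       end0 = integer(0), strand = character(0),
                       score = numeric(0))
  }
  hits <- hits[order(hits$contig, hits$start0, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' CpG offsets within motif hits
#'
#' For each hit, reports the 1-based motif positions whose genomic sequence
#' (read in motif orientation) carries a CpG, together with the
#' forward-strand coordinate of the CpG's C. On a plus hit, offset `k` means
#' forward positions `(start0 + k - 1, start0 + k)` spell CG; on a minus hit
#' offsets count from the motif's 5' end on the minus strand, so the same
#' forward CpG appears at offset `W - k_forward`.
#'
#' @param hits data.frame from [scan_motifs()]
#' @param genome a [Genome()]
#' @return data.frame, one row per (hit, offset): `hit` (row index into
#'   `hits`), `contig`, `start0`, `strand`, `score`, `offset`, `cpg_pos0`
#' @export
hit_cpg_offsets <- function(hits, genome) {
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    W <- h$end0 - h$start0
    idx <- genome$cpg_index[[h$contig]]
    cpg <- idx[idx >= h$start0 & idx < h$end0 - 1L]  # CG fully inside span
    if (length(cpg) == 0L) next
    k_forward <- cpg - h$start0 + 1L
    offset <- if (h$strand == "+") k_forward else W - k_forward
    out[[i]] <- data.frame(hit = i, contig = h$contig, start0 = h$start0,
                           strand = h$strand, score = h$score,
                           offset = offset, cpg_pos0 = cpg,
                           stringsAsFactors = FALSE)
  }
  res <- rbind_rows(out)
  if (is.null(res)) {
    res <- data.frame(hit = integer(0), contig = character(0),
                      start0 = integer(0), strand = character(0),
                      score = numeric(0), offset = integer(0),
                      cpg_pos0 = integer(0))
  }
  res
}

#' Methylation at selected motif positions
#'
#' Collects the betas of filtered CpG sites that map to each requested motif
#' offset in at least one hit, and compares the first two offsets with a
#' two-sample Wilcoxon rank-sum test (normal approximation with tie
#' correction). A CpG mapping to several hits at the same offset contributes
#' once per (hit, offset) by default; `unique_cpg` collapses to the
#' best-scoring hit per CpG.
#'
#' @param hit_offsets data.frame from [hit_cpg_offsets()]
#' @param sites filtered CpG sites (from [filter_sites()])
#' @param offsets motif positions to compare (1-based)
#' @param unique_cpg collapse each CpG to its best-scoring hit
#' @return list with `betas` (named list of beta vectors per offset),
#'   `medians`, `test` (htest from [stats::wilcox.test()] or NULL when a
#'   vector is empty)
#' @export
position_methylation <- function(hit_offsets, sites, offsets = c(2L, 12L),
                                 unique_cpg = FALSE) {
  ho <- hit_offsets[hit_offsets$offset %in% offsets, , drop = FALSE]
  if (unique_cpg && nrow(ho) > 0L) {
    key <- paste(ho$contig, ho$cpg_pos0, ho$offset)
    ho <- ho[order(key, -ho$score), , drop = FALSE]
    ho <- ho[!duplicated(paste(ho$contig, ho$cpg_pos0, ho$offset)), ,
             drop = FALSE]
  }
  site_key <- paste(sites$contig, sites$pos0)
  betas <- lapply(offsets, function(k) {
    sel <- ho[ho$offset == k, , drop = FALSE]
    b <- sites$beta[match(paste(sel$contig, sel$cpg_pos0), site_key)]
    b[!is.na(b)]
  })
  names(betas) <- paste0("C", offsets)
  medians <- vapply(betas, function(b) {
    if (length(b) == 0L) NA_real_ else stats::median(b)
  }, numeric(1))
  test <- NULL
  if (length(offsets) >= 2L && length(betas[[1L]]) > 0L &&
      length(betas[[2L]]) > 0L) {
    test <- stats::wilcox.test(betas[[1L]], betas[[2L]], exact = FALSE,
                               correct = FALSE)
  }
  list(betas = betas, medians = medians, test = test)
}

#' Paired comparison of the same CpGs measured by two assays
#'
#' Wilcoxon signed-rank test (normal approximation) on per-CpG beta pairs,
#' e.g. the same motif-position CpGs quantified by two different libraries.
#'
#' @param betaA,betaB equal-length beta vectors, matched per CpG
#' @return htest from [stats::wilcox.test()]
#' @export
paired_methylation_test <- function(betaA, betaB) {
  stopifnot(length(betaA) == length(betaB))
  stats::wilcox.test(betaA, betaB, paired = TRUE, exact = FALSE,
                     correct = FALSE)
}

#' Per-fragment co-methylation test at a CpG pair
#'
#' Counts the joint methylation states (MM, MU, UM, UU) of fragments with
#' non-AMBIG calls at both CpGs of `cpg_pair`, computes the expected counts
#' from the table's marginals under independence, and returns the Pearson
#' chi-square with one degree of freedom together with the observed and
#' expected fractions of doubly-methylated fragments. With fewer than two
#' informative fragments or a degenerate marginal the chi-square is NA.
#'
#' @param read_calls data.frame of calls (`query_name`, `contig`, `pos0`,
#'   `state`), e.g. from [call_read_methylation()] pooled over hits
#' @param cpg_pair 0-based coordinates of the two CpGs
#' @param contig contig the pair lives on (default: the only contig present)
#' @return a `ComethTable`: list with `counts` (MM, MU, UM, UU), `n`,
#'   `marginals`, `expected` (expected counts), `observed_mm_fraction`,
#'   `expected_mm_fraction`, `chi_square`, `df`, `p_value`
#' @export
comethylation_test <- function(read_calls, cpg_pair, contig = NULL) {
  if (is.null(contig)) {
    contig <- unique(read_calls$contig)
    if (length(contig) != 1L) stop("specify `contig`: several present")
  }
  rc <- read_calls[read_calls$contig == contig &
                     read_calls$pos0 %in% cpg_pair &
                     read_calls$state != "AMBIG", , drop = FALSE]
  c1 <- rc[rc$pos0 == cpg_pair[1L], c("query_name", "state")]
  c2 <- rc[rc$pos0 == cpg_pair[2L], c("query_name", "state")]
  shared <- intersect(c1$query_name, c2$query_name)
  s1 <- c1$state[match(shared, c1$query_name)] == "METH"
  s2 <- c2$state[match(shared, c2$query_name)] == "METH"
  counts <- c(MM = sum(s1 & s2), MU = sum(s1 & !s2),
              UM = sum(!s1 & s2), UU = sum(!s1 & !s2))
  n <- length(shared)
  p1 <- if (n > 0L) (counts[["MM"]] + counts[["MU"]]) / n else NA_real_
  p2 <- if (n > 0L) (counts[["MM"]] + counts[["UM"]]) / n else NA_real_
  expected <- c(MM = n * p1 * p2, MU = n * p1 * (1 - p2),
                UM = n * (1 - p1) * p2, UU = n * (1 - p1) * (1 - p2))
  degenerate <- n < 2L || is.na(p1) || p1 %in% c(0, 1) || p2 %in% c(0, 1)
  chi <- if (degenerate) NA_real_ else sum((counts - expected)^2 / expected)
  structure(list(
    counts = counts, n = n,
    marginals = c(p_meth_1 = p1, p_meth_2 = p2),
    expected = expected,
    observed_mm_fraction = if (n > 0L) counts[["MM"]] / n else NA_real_,
    expected_mm_fraction = if (n > 0L) p1 * p2 else NA_real_,
    chi_square = chi, df = 1L,
    p_value = if (is.na(chi)) NA_real_ else
      stats::pchisq(chi, df = 1L, lower.tail = FALSE)),
    class = "ComethTable")
}

#' @export
print.ComethTable <- function(x, ...) {
  cat("Per-fragment co-methylation table (n =", x$n, ")\n")
  print(x$counts)
  cat(sprintf("observed MM %.4f vs expected %.4f; chi-square = %s (df 1)\n",
              x$observed_mm_fraction, x$expected_mm_fraction,
              format(x$chi_square)))
  invisible(x)
}
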