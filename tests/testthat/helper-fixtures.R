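# Small in-code fixtures shared across test files.

# one-contig genome; default has a single CpG at pos0 2
tiny_genome <- function(seq = "TACGT", name = "c1") {
  Genome(stats::setNames(seq, name))
}

# one aligned fragment row in the read_alignments() layout; both mates span
# the same window unless pos2/seq2 are given
make_fragment <- function(contig = "c1", start0 = 0L, end0 = 5L,
                          strand = "OT", seq1 = "TACGT", qual1 = NULL,
                          pos1 = start0, seq2 = seq1, qual2 = NULL,
                          pos2 = pos1, query_name = "f1", mapq = 42L) {
  if (is.null(qual1)) qual1 <- strrep("I", nchar(seq1))
  if (is.null(qual2)) qual2 <- strrep("I", nchar(seq2))
  data.frame(query_name = query_name, contig = contig, start0 = start0,
             end0 = end0, bisulfite_strand = strand, mapq = mapq,
             seq1 = seq1, qual1 = qual1, pos1 = pos1,
             seq2 = seq2, qual2 = qual2, pos2 = pos2,
             stringsAsFactors = FALSE)
}

make_peaks <- function(contig, start0, end0, name = NULL) {
  if (is.null(name)) name <- sprintf("p%d", seq_along(start0))
  data.frame(contig = contig, start0 = as.integer(start0),
             end0 = as.integer(end0), name = name, score = 100,
             strand = ".", summit_offset = NA_integer_,
             stringsAsFactors = FALSE)
}

make_sites <- function(contig, pos0, count_meth, count_unmeth) {
  cov <- count_meth + count_unmeth
  data.frame(contig = contig, pos0 = as.integer(pos0),
             count_meth = as.integer(count_meth),
             count_unmeth = as.integer(count_unmeth),
             coverage = as.integer(cov),
             beta = ifelse(cov > 0, count_meth / cov, NA_real_),
             stringsAsFactors = FALSE)
}

# aggregate truth draws restricted to the (query_name, pos0) pairs that were
# actually called: the simulator-truth oracle for caller recovery
truth_beta_for_calls <- function(calls, truth_calls) {
  inf <- calls[calls$state != "AMBIG", , drop = FALSE]
  m <- match(paste(inf$query_name, inf$contig, inf$pos0),
             paste(truth_calls$query_name, truth_calls$contig,
                   truth_calls$pos0))
  stopifnot(!anyNA(m))
  key <- paste(inf$contig, inf$pos0)
  tb <- rowsum(truth_calls$methylated[m] + 0, key) /
    rowsum(rep(1, nrow(inf)), key)
  stats::setNames(tb[, 1L], rownames(tb))
}

# brute-force window scores: independent oracle for the PWM scanner
oracle_scan <- function(seq, log_odds, threshold) {
  W <- ncol(log_odds)
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(bases, c("A", "C", "G", "T"))
  rc <- log_odds[4:1, W:1, drop = FALSE]
  hits <- list()
  n <- length(bases) - W + 1L
  for (i in seq_len(max(n, 0L))) {
    win <- idx[i:(i + W - 1L)]
    if (anyNA(win)) next
    sf <- sum(log_odds[cbind(win, seq_len(W))])
    sr <- sum(rc[cbind(win, seq_len(W))])
    if (sf >= threshold) hits[[length(hits) + 1L]] <-
        data.frame(start0 = i - 1L, strand = "+", score = sf)
    if (sr >= threshold) hits[[length(hits) + 1L]] <-
        data.frame(start0 = i - 1L, strand = "-", score = sr)
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(start0 = integer(0), strand = character(0),
                      score = numeric(0))
  }
  out[order(out$start0, out$strand), , drop = FALSE]
}

# random count matrix for motif tests
random_pfm <- function(width, total = 20L) {
  m <- matrix(0, 4L, width)
  for (j in seq_len(width)) {
    m[, j] <- as.vector(stats::rmultinom(1L, total, rep(0.25, 4)))
  }
  rownames(m) <- c("A", "C", "G", "T")
  m
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
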