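#' Read a FASTA file into a Genome
#'
#' Wraps [Biostrings::readDNAStringSet()] and builds the CpG index. Headers
#' are truncated at the first whitespace, the usual convention for contig
#' names.
#'
#' @param path FASTA file
#' @return a [Genome()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) stop("duplicate contig name in ", path)
  Genome(seqs)
}

#' Write a Genome to FASTA
#' @param genome a [Genome()]
#' @param path output file
#' @param width line width
#' @return `path`, invisibly
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "Genome"))
  set <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read peak intervals from BED6 / ENCODE narrowPeak
#'
#' Accepts the 6-column BED and 10-column narrowPeak dialects
#' (tab-separated). Coordinates are kept 0-based half-open. The 10th column,
#' when present and non-negative, is the summit offset relative to the peak
#' start; the narrowPeak convention of `-1` means "no summit".
#'
#' Records with `start >= end` are rejected with a warning; non-integer
#' coordinates are a format error.
#'
#' @param path peak file
#' @return data.frame with columns `contig`, `start0`, `end0`, `name`,
#'   `score`, `strand`, and `summit_offset` (NA when absent)
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), start0 = integer(0),
                      end0 = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      summit_offset = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (!all(ncol %in% c(6L, 10L))) {
    stop("expected 6- or 10-column BED/narrowPeak records in ", path)
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  to_int <- function(x, what) {
    bad <- !grepl("^-?[0-9]+$", x)
    if (any(bad)) stop("non-integer ", what, " in ", path)
    as.integer(x)
  }
  start0 <- to_int(get(2L), "start")
  end0 <- to_int(get(3L), "end")
  summit <- rep(NA_integer_, length(fields))
  has10 <- ncol == 10L
  if (any(has10)) {
    s <- to_int(vapply(fields[has10], `[`, character(1), 10L), "summit")
    s[s < 0L] <- NA_integer_
    summit[has10] <- s
  }
  peaks <- data.frame(
    contig = get(1L), start0 = start0, end0 = end0,
    name = get(4L), score = suppressWarnings(as.numeric(get(5L))),
    strand = get(6L), summit_offset = summit,
    stringsAsFactors = FALSE)
  bad <- peaks$start0 >= peaks$end0
  if (any(bad)) {
    warning(sum(bad), " peak record(s) with start >= end rejected")
    peaks <- peaks[!bad, , drop = FALSE]
  }
  oob <- !is.na(peaks$summit_offset) &
    peaks$summit_offset >= (peaks$end0 - peaks$start0)
  if (any(oob)) {
    warning(sum(oob), " summit offset(s) outside the peak set to NA")
    peaks$summit_offset[oob] <- NA_integer_
  }
  rownames(peaks) <- NULL
  peaks
}

#' Write peaks as narrowPeak
#' @param peaks data.frame as returned by [read_narrowpeak()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_narrowpeak <- function(peaks, path) {
  summit <- peaks$summit_offset
  if (is.null(summit)) summit <- rep(NA_integer_, nrow(peaks))
  summit <- ifelse(is.na(summit), -1L, summit)
  strand <- if (is.null(peaks$strand)) rep(".", nrow(peaks)) else peaks$strand
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t0\t-1\t-1\t%d",
                   peaks$contig, peaks$start0, peaks$end0, peaks$name,
                   format(peaks$score, trim = TRUE), strand, summit)
  writeLines(lines, path)
  invisible(path)
}

#' Read a Bismark-style coverage file into CpG sites
#'
#' Expected columns: contig, start (1-based), end, methylation percentage,
#' methylated count, unmethylated count. Positions are converted to 0-based;
#' beta is recomputed from the counts (the percentage column is advisory and
#' a deviation above 0.5 percentage points triggers a warning). With
#' `merge_strands` and a genome, a record sitting on the G of a CpG (position
#' p whose p-1 is an indexed C) is folded onto the forward-strand C at p-1.
#'
#' @param path coverage file
#' @param merge_strands fold G-strand records onto the C position (needs
#'   `genome`)
#' @param genome optional [Genome()] used to recognise G-strand records
#' @return data.frame of CpG sites: `contig`, `pos0`, `count_meth`,
#'   `count_unmeth`, `coverage`, `beta` (NA at coverage 0)
#' @export
read_bismark_cov <- function(path, merge_strands = FALSE, genome = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("contig", "start1", "end1",
                                         "pct", "count_meth", "count_unmeth"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric", "integer", "integer"))
  if (any(tab$count_meth < 0L | tab$count_unmeth < 0L)) {
    stop("negative counts in ", path)
  }
  cov <- tab$count_meth + tab$count_unmeth
  beta <- ifelse(cov > 0L, tab$count_meth / cov, NA_real_)
  stated <- tab$pct / 100
  off <- cov > 0L & abs(stated - beta) * 100 > 0.5
  if (any(off)) {
    warning(sum(off), " record(s) whose % column disagrees with counts by > 0.5")
  }
  sites <- data.frame(contig = tab$contig, pos0 = tab$start1 - 1L,
                      count_meth = tab$count_meth,
                      count_unmeth = tab$count_unmeth,
                      coverage = cov, beta = beta,
                      stringsAsFactors = FALSE)
  if (merge_strands) {
    if (is.null(genome)) stop("merge_strands requires a genome")
    sites <- destrand_sites(sites, genome)
  }
  sites
}

# Fold G-strand coverage records onto the forward-strand C of their CpG.
# A record at p is G-strand evidence iff p-1 is an indexed CpG C and p is not.
destrand_sites <- function(sites, genome) {
  is_c <- logical(nrow(sites))
  for (ctg in unique(sites$contig)) {
    idx <- genome$cpg_index[[ctg]]
    sel <- sites$contig == ctg
    is_c[sel] <- sites$pos0[sel] %in% idx
  }
  pos_c <- ifelse(is_c, sites$pos0, sites$pos0 - 1L)
  key <- paste(sites$contig, pos_c)
  agg_m <- rowsum(sites$count_meth, key)
  agg_u <- rowsum(sites$count_unmeth, key)
  first <- !duplicated(key)
  out <- data.frame(contig = sites$contig[first],
                    pos0 = pos_c[first],
                    count_meth = as.integer(agg_m[key[first], 1L]),
                    count_unmeth = as.integer(agg_u[key[first], 1L]),
                    stringsAsFactors = FALSE)
  out$coverage <- out$count_meth + out$count_unmeth
  out$beta <- ifelse(out$coverage > 0L, out$count_meth / out$coverage, NA_real_)
  out[order(out$contig, out$pos0), , drop = FALSE]
}

#' Write CpG sites as a Bismark-style coverage file
#' @param sites data.frame as from [read_bismark_cov()] or
#'   [aggregate_sites()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bismark_cov <- function(sites, path) {
  pct <- ifelse(sites$coverage > 0L, 100 * sites$count_meth / sites$coverage, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   sites$contig, sites$pos0 + 1L, sites$pos0 + 1L,
                   format(pct, trim = TRUE, digits = 10),
                   sites$count_meth, sites$count_unmeth)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph methylation track (read-only, counts unknown)
#'
#' bedGraph is 0-based half-open and carries only a value column; counts are
#' returned as NA so downstream coverage filters treat the sites as
#' count-free.
#'
#' @param path bedGraph file
#' @return data.frame with `contig`, `pos0`, `count_meth`, `count_unmeth`,
#'   `coverage` (all NA), `beta` (value / 100)
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    contig = vapply(fields, `[`, character(1), 1L),
    pos0 = as.integer(vapply(fields, `[`, character(1), 2L)),
    count_meth = NA_integer_, count_unmeth = NA_integer_,
    coverage = NA_integer_,
    beta = as.numeric(vapply(fields, `[`, character(1), 4L)) / 100,
    stringsAsFactors = FALSE)
}

#' Read aligned directional bisulfite paired-end fragments
#'
#' Reads a SAM or BAM file (SAM text is converted on the fly with
#' [Rsamtools::asBam()]), keeps primary proper pairs, derives the bisulfite
#' strand from the flag combination (read1 forward / read2 reverse = OT,
#' original top; read1 reverse / read2 forward = OB, original bottom), drops
#' fragments whose minimum mate MAPQ is below `mapq_min`, and collapses
#' duplicates (identical contig, start, end and bisulfite strand, which keeps
#' OT and OB molecules at the same coordinates distinct) keeping the first by
#' read name.
#'
#' @param path SAM or BAM file
#' @param mapq_min minimum mapping quality (fragments below are dropped)
#' @param dedup collapse coordinate duplicates
#' @return data.frame of fragments, one row per retained pair: `query_name`,
#'   `contig`, `start0`, `end0`, `bisulfite_strand` ("OT"/"OB"), `mapq`, and
#'   per-mate `seq1`, `qual1`, `pos1` (0-based mate start), `seq2`, `qual2`,
#'   `pos2`. Attribute `counts` logs records skipped/dropped at each filter.
#' @export
read_alignments <- function(path, mapq_min = 30L, dedup = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  recs <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  n_in <- length(recs$qname)
  flag <- recs$flag
  paired <- bitwAnd(flag, 0x1L) > 0L
  proper <- bitwAnd(flag, 0x2L) > 0L
  secondary <- bitwAnd(flag, 0x100L) > 0L | bitwAnd(flag, 0x800L) > 0L
  unmapped <- bitwAnd(flag, 0x4L) > 0L
  keep <- paired & proper & !secondary & !unmapped
  n_skipped <- sum(!keep)
  reads <- data.frame(
    qname = recs$qname[keep],
    flag = flag[keep],
    contig = as.character(recs$rname[keep]),
    pos0 = recs$pos[keep] - 1L,
    mapq = recs$mapq[keep],
    width = cigar_ref_width(recs$cigar[keep]),
    seq = as.character(recs$seq)[keep],
    qual = as.character(recs$qual)[keep],
    stringsAsFactors = FALSE)
  reads$is_read1 <- bitwAnd(reads$flag, 0x40L) > 0L
  reads$rev <- bitwAnd(reads$flag, 0x10L) > 0L

  # pair mates: sort read1-before-read2 within qname, then pair adjacent rows
  reads <- reads[order(reads$qname, !reads$is_read1), , drop = FALSE]
  runs <- rle(reads$qname)
  pair_ok <- rep(runs$lengths == 2L, runs$lengths)
  i1 <- which(pair_ok & !duplicated(reads$qname))
  i2 <- i1 + 1L
  good <- reads$is_read1[i1] & !reads$is_read1[i2]
  n_unpaired <- sum(runs$lengths != 2L) + sum(!good)
  if (n_unpaired > 0L) {
    warning(n_unpaired, " read name(s) without a complete primary pair skipped")
  }
  i1 <- i1[good]
  i2 <- i2[good]
  r1f <- !reads$rev[i1]
  r2f <- !reads$rev[i2]
  strand <- ifelse(r1f & !r2f, "OT", ifelse(!r1f & r2f, "OB", NA_character_))
  frags <- data.frame(
    query_name = reads$qname[i1], contig = reads$contig[i1],
    start0 = pmin(reads$pos0[i1], reads$pos0[i2]),
    end0 = pmax(reads$pos0[i1] + reads$width[i1],
                reads$pos0[i2] + reads$width[i2]),
    bisulfite_strand = strand,
    mapq = pmin(reads$mapq[i1], reads$mapq[i2]),
    seq1 = reads$seq[i1], qual1 = reads$qual[i1], pos1 = reads$pos0[i1],
    seq2 = reads$seq[i2], qual2 = reads$qual[i2], pos2 = reads$pos0[i2],
    stringsAsFactors = FALSE)
  n_badstrand <- sum(is.na(frags$bisulfite_strand))
  if (n_badstrand > 0L) {
    warning(n_badstrand, " fragment(s) with unknown strand flag combination dropped")
    frags <- frags[!is.na(frags$bisulfite_strand), , drop = FALSE]
  }
  n_lowmapq <- sum(frags$mapq < mapq_min)
  frags <- frags[frags$mapq >= mapq_min, , drop = FALSE]
  n_dup <- 0L
  if (dedup && nrow(frags) > 0L) {
    frags <- frags[order(frags$contig, frags$start0, frags$end0,
                         frags$bisulfite_strand, frags$query_name), ,
                   drop = FALSE]
    key <- paste(frags$contig, frags$start0, frags$end0,
                 frags$bisulfite_strand)
    n_dup <- sum(duplicated(key))
    frags <- frags[!duplicated(key), , drop = FALSE]
  }
  rownames(frags) <- NULL
  attr(frags, "counts") <- c(records_in = n_in, records_skipped = n_skipped,
                             unpaired = n_unpaired,
                             unknown_strand = n_badstrand,
                             low_mapq = n_lowmapq, duplicates = n_dup,
                             fragments_out = nrow(frags))
  frags
}

# Reference-consumed width of simple CIGARs (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1L]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    lens <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(lens[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write fragments as a SAM file
#'
#' Emits one proper pair per fragment with flags that encode the bisulfite
#' strand the way [read_alignments()] infers it (OT: 99/147, OB: 83/163).
#'
#' @param fragments data.frame in the layout of [read_alignments()]
#' @param path output SAM file
#' @param genome a [Genome()] supplying the header contig lengths
#' @return `path`, invisibly
#' @export
write_sam <- function(fragments, path, genome) {
  lens <- contig_lengths(genome)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  f <- fragments
  ot <- f$bisulfite_strand == "OT"
  flag1 <- ifelse(ot, 99L, 83L)
  flag2 <- ifelse(ot, 147L, 163L)
  tlen <- f$end0 - f$start0
  sign1 <- ifelse(f$pos1 <= f$pos2, tlen, -tlen)
  rec <- function(qn, flag, contig, pos0, mapq, seq, qual, mpos0, tl) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
            qn, flag, contig, pos0 + 1L, mapq, nchar(seq), mpos0 + 1L, tl,
            seq, qual)
  }
  lines1 <- rec(f$query_name, flag1, f$contig, f$pos1, f$mapq, f$seq1,
                f$qual1, f$pos2, sign1)
  lines2 <- rec(f$query_name, flag2, f$contig, f$pos2, f$mapq, f$seq2,
                f$qual2, f$pos1, -sign1)
  body <- character(2L * nrow(f))
  if (nrow(f) > 0L) {
    body[seq(1L, by = 2L, length.out = nrow(f))] <- lines1
    body[seq(2L, by = 2L, length.out = nrow(f))] <- lines2
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read minimal gene models
#'
#' Tab-separated with header: `gene`, `contig`, `strand`, `tss` (0-based),
#' `start0`, `end0`. Comment lines start with '#'.
#'
#' @param path gene model TSV
#' @return data.frame of gene models
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "contig", "strand", "tss", "start0", "end0")
  if (!all(need %in% names(tab))) {
    stop("gene model file must have columns: ", paste(need, collapse = ", "))
  }
  tab
}
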