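#' Call per-fragment CpG methylation states
#'
#' Strand-aware bisulfite calling on directional libraries. For every indexed
#' CpG a fragment overlaps, the informative base is read in forward-genome
#' orientation: on OT (original top) molecules at the C position, where 'C'
#' means methylated and 'T' unmethylated; on OB (original bottom) at the
#' paired G (C position + 1), where 'G' means methylated and 'A'
#' unmethylated. Any other base, or a base below `min_base_quality`, yields
#' AMBIG. When the mates overlap a CpG, the mate with the higher base quality
#' wins; ties go to read 1. One fragment contributes at most one call per
#' CpG, so mate overlap never double-counts a molecule.
#'
#' @param fragments data.frame in the [read_alignments()] layout
#' @param genome a [Genome()]
#' @param min_base_quality minimum Phred base quality for a call
#' @return data.frame of read calls: `query_name`, `contig`, `pos0`
#'   (forward-strand C position), `strand` ("OT"/"OB"), `state`
#'   ("METH"/"UNMETH"/"AMBIG")
#' @export
call_read_methylation <- function(fragments, genome, min_base_quality = 20L) {
  stopifnot(inherits(genome, "Genome"))
  missing_ctg <- setdiff(unique(fragments$contig), names(genome$sequences))
  if (length(missing_ctg) > 0L) {
    stop("fragment contig(s) absent from genome: ",
         paste(missing_ctg, collapse = ", "))
  }
  n <- nrow(fragments)
  o_qn <- vector("list", n); o_pos <- vector("list", n)
  o_str <- vector("list", n); o_state <- vector("list", n)
  for (i in seq_len(n)) {
    ctg <- fragments$contig[i]
    cpgs <- genome$cpg_index[[ctg]]
    cpgs <- cpgs[cpgs >= fragments$start0[i] & cpgs < fragments$end0[i]]
    if (length(cpgs) == 0L) next
    ot <- fragments$bisulfite_strand[i] == "OT"
    target <- if (ot) cpgs else cpgs + 1L
    b1 <- mate_base(fragments$seq1[i], fragments$qual1[i],
                    fragments$pos1[i], target)
    b2 <- mate_base(fragments$seq2[i], fragments$qual2[i],
                    fragments$pos2[i], target)
    use1 <- !is.na(b1$base) & (is.na(b2$base) | b1$qual >= b2$qual)
    base <- ifelse(use1, b1$base, b2$base)
    qual <- ifelse(use1, b1$qual, b2$qual)
    state <- if (ot) {
      ifelse(base == "C", "METH", ifelse(base == "T", "UNMETH", "AMBIG"))
    } else {
      ifelse(base == "G", "METH", ifelse(base == "A", "UNMETH", "AMBIG"))
    }
    state[is.na(base) | qual < min_base_quality] <- "AMBIG"
    keep <- !is.na(base)   # CpG in the fragment span but not under either mate
    if (!any(keep)) next
    o_qn[[i]] <- rep(fragments$query_name[i], sum(keep))
    o_pos[[i]] <- cpgs[keep]
    o_str[[i]] <- rep(fragments$bisulfite_strand[i], sum(keep))
    o_state[[i]] <- state[keep]
  }
  qn <- unlist(o_qn, use.names = FALSE)
  if (is.null(qn)) qn <- character(0)
  calls <- data.frame(
    query_name = qn,
    contig = rep(fragments$contig,
                 vapply(o_pos, length, integer(1)))[seq_along(qn)],
    pos0 = as.integer(unlist(o_pos, use.names = FALSE)),
    strand = as.character(unlist(o_str, use.names = FALSE))[seq_along(qn)],
    state = as.character(unlist(o_state, use.names = FALSE))[seq_along(qn)],
    stringsAsFactors = FALSE)
  calls
}

# base + Phred quality of one mate at given 0-based genome positions
mate_base <- function(seq, qual, pos0, target) {
  off <- target - pos0 + 1L
  inside <- off >= 1L & off <= nchar(seq)
  base <- rep(NA_character_, length(target))
  q <- rep(-1L, length(target))
  if (any(inside)) {
    base[inside] <- substring(seq, off[inside], off[inside])
    q[inside] <- utf8ToInt(qual)[off[inside]] - 33L
  }
  list(base = base, qual = q)
}

#' Aggregate read calls to CpG sites
#'
#' Sums methylated / unmethylated calls per CpG; AMBIG calls are excluded
#' from both counts. With `merge_strands` (the default) OT- and OB-derived
#' evidence pools onto the forward-strand C position — counts are summed and
#' beta recomputed, never averaged — so coverage weighting stays exact.
#' With `merge_strands = FALSE` sites are reported per (position, strand).
#' Sites with zero informative coverage are omitted.
#'
#' @param calls data.frame from [call_read_methylation()]
#' @param merge_strands pool both strands onto the C position
#' @return data.frame of CpG sites: `contig`, `pos0`, (`strand`,)
#'   `count_meth`, `count_unmeth`, `coverage`, `beta`
#' @export
aggregate_sites <- function(calls, merge_strands = TRUE) {
  inf <- calls[calls$state != "AMBIG", , drop = FALSE]
  if (nrow(inf) == 0L) {
    out <- data.frame(contig = character(0), pos0 = integer(0),
                      count_meth = integer(0), count_unmeth = integer(0),
                      coverage = integer(0), beta = numeric(0))
    if (!merge_strands) out$strand <- character(0)
    return(out)
  }
  key <- if (merge_strands) {
    paste(inf$contig, inf$pos0)
  } else {
    paste(inf$contig, inf$pos0, inf$strand)
  }
  m <- rowsum((inf$state == "METH") + 0L, key)
  u <- rowsum((inf$state == "UNMETH") + 0L, key)
  first <- !duplicated(key)
  out <- data.frame(contig = inf$contig[first], pos0 = inf$pos0[first],
                    stringsAsFactors = FALSE)
  if (!merge_strands) out$strand <- inf$strand[first]
  out$count_meth <- as.integer(m[key[first], 1L])
  out$count_unmeth <- as.integer(u[key[first], 1L])
  out$coverage <- out$count_meth + out$count_unmeth
  out$beta <- out$count_meth / out$coverage
  out <- out[order(out$contig, out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter CpG sites to covered positions inside peaks
#'
#' Keeps sites with `coverage >= min_coverage` whose C position lies within
#' at least one peak interval (0-based half-open, so a site at `peak end` is
#' outside). Retained sites are annotated with the comma-joined names of the
#' containing peak(s).
#'
#' @param sites data.frame from [aggregate_sites()] or [read_bismark_cov()]
#' @param peaks data.frame as from [read_narrowpeak()]
#' @param min_coverage minimum informative reads per site
#' @return the retained sites with an extra `peaks` column
#' @export
filter_sites <- function(sites, peaks, min_coverage = 5L) {
  if (nrow(peaks) == 0L) {
    warning("empty peak list: no sites retained")
    out <- sites[integer(0), , drop = FALSE]
    out$peaks <- character(0)
    return(out)
  }
  keep_cov <- !is.na(sites$coverage) & sites$coverage >= min_coverage
  sites <- sites[keep_cov, , drop = FALSE]
  if (nrow(sites) == 0L) {
    sites$peaks <- character(0)
    return(sites)
  }
  site_gr <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(start = sites$pos0 + 1L, width = 1L))
  peak_gr <- GenomicRanges::GRanges(
    peaks$contig, IRanges::IRanges(start = peaks$start0 + 1L,
                                   end = peaks$end0))
  ov <- GenomicRanges::findOverlaps(site_gr, peak_gr)
  hit_site <- S4Vectors::queryHits(ov)
  hit_peak <- S4Vectors::subjectHits(ov)
  idx <- sort(unique(hit_site))
  names_by_site <- vapply(split(peaks$name[hit_peak], hit_site),
                          paste, character(1), collapse = ",")
  out <- sites[idx, , drop = FALSE]
  out$peaks <- unname(names_by_site[as.character(idx)])
  rownames(out) <- NULL
  out
}
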