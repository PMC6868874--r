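#' Mean CpG methylation per peak
#'
#' Unweighted mean of site betas per peak (each CpG one vote). Sites must
#' already have passed [filter_sites()], which attaches the containing peak
#' names; a site inside several peaks contributes to each. Peaks with no
#' qualifying CpG are omitted.
#'
#' @param peaks data.frame as from [read_narrowpeak()]
#' @param filtered_sites output of [filter_sites()]
#' @return data.frame: `name`, `n_cpgs_used`, `mean_beta`
#' @export
peak_mean_methylation <- function(peaks, filtered_sites) {
  if (nrow(filtered_sites) == 0L) {
    return(data.frame(name = character(0), n_cpgs_used = integer(0),
                      mean_beta = numeric(0)))
  }
  expand <- strsplit(filtered_sites$peaks, ",", fixed = TRUE)
  peak_of <- unlist(expand, use.names = FALSE)
  beta <- rep(filtered_sites$beta, lengths(expand))
  n <- vapply(split(beta, peak_of), length, integer(1))
  mb <- vapply(split(beta, peak_of), mean, numeric(1))
  out <- data.frame(name = names(n), n_cpgs_used = as.integer(n),
                    mean_beta = unname(mb), stringsAsFactors = FALSE)
  out <- out[match(peaks$name[peaks$name %in% out$name], out$name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-assay quadrant classification of peak methylation
#'
#' Labels every peak shared between two per-peak methylation tables (e.g.
#' the same peak set quantified by two assays) by comparing `mean_beta` to
#' `threshold` on each axis: `low` is strictly below the threshold, values at
#' or above it are `high`. Quadrant names read with assay A on the x axis and
#' assay B on the y axis: `bottom_left` (low/low), `top_left` (low A, high
#' B), `top_right` (high/high), `bottom_right` (high A, low B).
#'
#' @param tableA,tableB data.frames from [peak_mean_methylation()]
#' @param threshold low/high split applied to both axes
#' @return list with `per_peak` (name, beta_A, beta_B, quadrant) and
#'   `counts` (named integer vector over the four quadrants)
#' @export
quadrant_counts <- function(tableA, tableB, threshold = 0.5) {
  shared <- intersect(tableA$name, tableB$name)
  if (length(shared) == 0L) stop("no shared peaks between the two tables")
  a <- tableA$mean_beta[match(shared, tableA$name)]
  b <- tableB$mean_beta[match(shared, tableB$name)]
  low_a <- a < threshold
  low_b <- b < threshold
  quadrant <- ifelse(low_a & low_b, "bottom_left",
              ifelse(low_a & !low_b, "top_left",
              ifelse(!low_a & !low_b, "top_right", "bottom_right")))
  lev <- c("bottom_left", "top_left", "top_right", "bottom_right")
  counts <- table(factor(quadrant, levels = lev))
  list(per_peak = data.frame(name = shared, beta_A = a, beta_B = b,
                             quadrant = quadrant, stringsAsFactors = FALSE),
       counts = stats::setNames(as.integer(counts), lev))
}

#' Jaccard index of two interval sets
#'
#' Intervals are merged to disjoint form per contig; the index is total
#' intersection bp over total union bp.
#'
#' @param peaksA,peaksB data.frames with `contig`, `start0`, `end0`
#' @return a fraction in `[0, 1]`
#' @export
interval_jaccard <- function(peaksA, peaksB) {
  if (nrow(peaksA) == 0L && nrow(peaksB) == 0L) {
    stop("both interval sets are empty")
  }
  gr <- function(p) GenomicRanges::reduce(GenomicRanges::GRanges(
    p$contig, IRanges::IRanges(start = p$start0 + 1L, end = p$end0)))
  a <- gr(peaksA)
  b <- gr(peaksB)
  inter <- sum(IRanges::width(GenomicRanges::intersect(a, b)))
  uni <- sum(IRanges::width(GenomicRanges::union(a, b)))
  inter / uni
}

#' Pearson correlation of binned fragment counts
#'
#' Tiles the genome with fixed-size bins, counts fragment midpoints per bin
#' in each sample, and returns the Pearson correlation across bins.
#'
#' @param fragsA,fragsB fragment data.frames (`contig`, `start0`, `end0`)
#' @param genome a [Genome()] (defines the tiling)
#' @param bin_size bin width in bp
#' @return Pearson r
#' @export
binned_pearson <- function(fragsA, fragsB, genome, bin_size = 10000L) {
  lens <- contig_lengths(genome)
  count_bins <- function(fr) {
    unlist(lapply(names(lens), function(ctg) {
      nb <- ceiling(lens[[ctg]] / bin_size)
      sel <- fr$contig == ctg
      mid <- (fr$start0[sel] + fr$end0[sel]) %/% 2L
      tabulate(mid %/% bin_size + 1L, nbins = nb)
    }), use.names = FALSE)
  }
  x <- count_bins(fragsA)
  y <- count_bins(fragsB)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance bin counts: correlation undefined")
  }
  stats::cor(x, y)
}

#' Annotate regions as promoter / intragenic / intergenic
#'
#' Precedence promoter > intragenic > intergenic. A region is `promoter` when
#' it overlaps a window of `promoter_flank` bp on both sides of a TSS,
#' `intragenic` when it overlaps a gene body, otherwise `intergenic`. A
#' `promoter_distal` column additionally reports whether an intergenic region
#' lies more than `intergenic_min_dist` bp from every promoter window; the
#' label itself stays `intergenic` either way. Regions on contigs absent
#' from the gene models are labeled intergenic with a warning.
#'
#' @param regions data.frame with `contig`, `start0`, `end0`
#' @param gene_models data.frame from [read_gene_models()]
#' @param promoter_flank half-width of the promoter window around the TSS
#' @param intergenic_min_dist distance used for the `promoter_distal` flag
#' @return `regions` with `label` and `promoter_distal` columns
#' @export
annotate_regions <- function(regions, gene_models, promoter_flank = 3000L,
                             intergenic_min_dist = 1000L) {
  missing_ctg <- setdiff(unique(regions$contig), unique(gene_models$contig))
  if (length(missing_ctg) > 0L) {
    warning("region contig(s) absent from gene models labeled intergenic: ",
            paste(missing_ctg, collapse = ", "))
  }
  reg <- GenomicRanges::GRanges(
    regions$contig, IRanges::IRanges(start = regions$start0 + 1L,
                                     end = regions$end0))
  prom <- GenomicRanges::GRanges(
    gene_models$contig,
    IRanges::IRanges(start = pmax(1L, gene_models$tss - promoter_flank + 1L),
                     end = gene_models$tss + promoter_flank + 1L))
  body <- GenomicRanges::GRanges(
    gene_models$contig, IRanges::IRanges(start = gene_models$start0 + 1L,
                                         end = gene_models$end0))
  # contigs absent from the models already warned about above; the ranges
  # machinery would warn again on disjoint seqlevels
  ov_prom <- suppressWarnings(GenomicRanges::countOverlaps(reg, prom)) > 0L
  ov_body <- suppressWarnings(GenomicRanges::countOverlaps(reg, body)) > 0L
  label <- ifelse(ov_prom, "promoter",
           ifelse(ov_body, "intragenic", "intergenic"))
  nearest <- suppressWarnings(GenomicRanges::distanceToNearest(reg, prom))
  d <- rep(NA_integer_, length(reg))
  d[S4Vectors::queryHits(nearest)] <- S4Vectors::mcols(nearest)$distance
  out <- regions
  out$label <- label
  out$promoter_distal <- is.na(d) | d > intergenic_min_dist
  out
}

#' Fragment length histogram
#'
#' Counts fragment lengths (`end0 - start0`), excluding lengths above
#' `max_length`, and reports the mean and median of the retained lengths.
#'
#' @param fragments fragment data.frame
#' @param max_length maximum fragment length retained
#' @return list with `histogram` (data.frame `length`, `count`), `mean`,
#'   `median`, `n_excluded`
#' @export
fragment_length_histogram <- function(fragments, max_length = 1000L) {
  len <- fragments$end0 - fragments$start0
  n_exc <- sum(len > max_length)
  len <- len[len <= max_length]
  if (length(len) == 0L) {
    return(list(histogram = data.frame(length = integer(0), count = integer(0)),
                mean = NA_real_, median = NA_real_, n_excluded = n_exc))
  }
  tab <- table(len)
  list(histogram = data.frame(length = as.integer(names(tab)),
                              count = as.integer(tab)),
       mean = mean(len), median = stats::median(len), n_excluded = n_exc)
}
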