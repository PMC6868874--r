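#' Configuration of an end-to-end pipeline run
#'
#' Collects input paths and every tunable threshold. The configuration is
#' serialized verbatim (as TSV key-value pairs) into the output directory so
#' a run can be reproduced from its outputs alone.
#'
#' @param fasta reference FASTA path
#' @param alignments SAM/BAM path
#' @param peaks narrowPeak/BED path
#' @param outdir output directory
#' @param mapq_min minimum fragment mapping quality
#' @param min_base_quality minimum base quality for a methylation call
#' @param min_coverage minimum reads per retained CpG site
#' @param merge_strands pool OT/OB evidence per CpG
#' @param quadrant_threshold low/high split for [quadrant_counts()]
#' @param motif_pvalue tail probability for [pwm_score_threshold()]
#' @param pfm optional JASPAR PFM path enabling the motif stage
#' @param motif_offsets CpG-capable motif positions compared when the motif
#'   stage runs
#' @param thresholds a [grouping_thresholds()]
#' @param seed integer seed recorded in the run log
#' @return a `RunConfig` list
#' @export
run_config <- function(fasta, alignments, peaks, outdir,
                       mapq_min = 30L, min_base_quality = 20L,
                       min_coverage = 5L, merge_strands = TRUE,
                       quadrant_threshold = 0.5, motif_pvalue = 1e-4,
                       pfm = NULL, motif_offsets = c(2L, 12L),
                       thresholds = grouping_thresholds(), seed = 1L) {
  stopifnot(min_coverage >= 1L, quadrant_threshold > 0, quadrant_threshold < 1,
            motif_pvalue > 0, motif_pvalue < 1)
  structure(list(fasta = fasta, alignments = alignments, peaks = peaks,
                 outdir = outdir, mapq_min = as.integer(mapq_min),
                 min_base_quality = as.integer(min_base_quality),
                 min_coverage = as.integer(min_coverage),
                 merge_strands = merge_strands,
                 quadrant_threshold = quadrant_threshold,
                 motif_pvalue = motif_pvalue, pfm = pfm,
                 motif_offsets = as.integer(motif_offsets),
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the downstream pipeline end to end
#'
#' Executes alignment ingest, methylation calling, site aggregation, the
#' peak/coverage filter, per-peak methylation, grouping, and (when a PFM is
#' configured) the motif stage: scanning, CpG-offset annotation,
#' position-methylation comparison and the co-methylation test pooled over
#' hits carrying both requested offsets. Writes `sites.cov`,
#' `filtered_sites.tsv`, `peak_methylation.tsv`, `groups.tsv`, `qc.tsv`,
#' motif TSVs when enabled, `config.tsv`, and `run.log` with record counts at
#' every stage.
#'
#' @param config a [run_config()]
#' @return (invisibly) list with every stage's table plus `stage_counts`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  log_lines <- c(sprintf("tagmeth %s", as.character(utils::packageVersion("tagmeth"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("started: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  stage_counts <- c()
  note <- function(stage, n) {
    stage_counts[[stage]] <<- n
    log_lines <<- c(log_lines, sprintf("%s: %d", stage, n))
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", stage,
                                      conditionMessage(e))), log_path)
      stop(sprintf("pipeline failed at stage '%s' (see %s): %s", stage,
                   log_path, conditionMessage(e)), call. = FALSE)
    })
  }

  genome <- run_stage("read_fasta", read_fasta(config$fasta))
  note("cpgs_in_genome", sum(lengths(genome$cpg_index)))
  peaks <- run_stage("read_peaks", read_narrowpeak(config$peaks))
  note("peaks_in", nrow(peaks))
  fragments <- run_stage("read_alignments",
                         read_alignments(config$alignments,
                                         mapq_min = config$mapq_min))
  for (nm in names(attr(fragments, "counts"))) {
    note(paste0("alignments_", nm), attr(fragments, "counts")[[nm]])
  }
  calls <- run_stage("call_methylation",
                     call_read_methylation(fragments, genome,
                                           config$min_base_quality))
  note("read_calls", nrow(calls))
  sites <- run_stage("aggregate_sites",
                     aggregate_sites(calls, config$merge_strands))
  note("sites", nrow(sites))
  filtered <- run_stage("filter_sites",
                        filter_sites(sites, peaks, config$min_coverage))
  note("filtered_sites", nrow(filtered))
  peak_meth <- run_stage("peak_methylation",
                         peak_mean_methylation(peaks, filtered))
  note("peaks_with_cpgs", nrow(peak_meth))
  grp <- run_stage("groups", group_summary(filtered, config$thresholds))
  note("grouped_sites", sum(grp$summary$count[grp$summary$label %in%
                                                c("G1", "G2", "G3", "G4")]))
  flh <- run_stage("fragment_lengths", fragment_length_histogram(fragments))

  motif <- NULL
  if (!is.null(config$pfm)) {
    motif <- run_stage("motifs", {
      counts <- read_jaspar_pfm(config$pfm)
      pwm <- pwm_from_counts(counts)
      thr <- pwm_score_threshold(pwm, pvalue = config$motif_pvalue)
      hits <- scan_motifs(genome, pwm, thr,
                          regions = peaks[, c("contig", "start0", "end0")])
      offs <- hit_cpg_offsets(hits, genome)
      posmeth <- position_methylation(offs, filtered,
                                      offsets = config$motif_offsets)
      cometh <- motif_comethylation(offs, calls, config$motif_offsets)
      list(pwm = pwm, threshold = thr, hits = hits, offsets = offs,
           position_methylation = posmeth, comethylation = cometh)
    })
    note("motif_hits", nrow(motif$hits))
  }

  # outputs
  write_bismark_cov(sites, file.path(config$outdir, "sites.cov"))
  write_tsv_commented(filtered, file.path(config$outdir, "filtered_sites.tsv"),
                      comment = sprintf("min_coverage=%d", config$min_coverage))
  write_tsv_commented(peak_meth, file.path(config$outdir, "peak_methylation.tsv"))
  write_tsv_commented(grp$sites, file.path(config$outdir, "groups.tsv"))
  qc <- data.frame(metric = c("fragment_length_mean", "fragment_length_median",
                              "fragments_over_max_length"),
                   value = c(flh$mean, flh$median, flh$n_excluded))
  write_tsv_commented(qc, file.path(config$outdir, "qc.tsv"))
  if (!is.null(motif)) {
    write_tsv_commented(motif$hits, file.path(config$outdir, "hits.tsv"),
                        comment = sprintf("threshold=%g", motif$threshold))
    write_tsv_commented(motif$offsets, file.path(config$outdir,
                                                 "hit_cpg_offsets.tsv"))
  }
  cfg_flat <- data.frame(
    key = c("fasta", "alignments", "peaks", "mapq_min", "min_base_quality",
            "min_coverage", "merge_strands", "quadrant_threshold",
            "motif_pvalue", "seed"),
    value = c(config$fasta, config$alignments, config$peaks, config$mapq_min,
              config$min_base_quality, config$min_coverage,
              config$merge_strands, config$quadrant_threshold,
              config$motif_pvalue, config$seed))
  write_tsv_commented(cfg_flat, file.path(config$outdir, "config.tsv"))
  writeLines(c(log_lines, "status: ok"), log_path)

  invisible(list(genome = genome, peaks = peaks, fragments = fragments,
                 calls = calls, sites = sites, filtered_sites = filtered,
                 peak_methylation = peak_meth, groups = grp,
                 fragment_lengths = flh, motif = motif,
                 stage_counts = unlist(stage_counts)))
}

# Pool the co-methylation test over all hits that carry both requested
# offsets: for each such hit the (C_a, C_b) coordinate pair enters one joint
# table keyed by fragment, then the chi-square is computed on the pooled
# counts. Returns NULL when no hit carries both offsets.
motif_comethylation <- function(hit_offsets, calls, offsets = c(2L, 12L)) {
  ho <- hit_offsets[hit_offsets$offset %in% offsets, , drop = FALSE]
  if (nrow(ho) == 0L) return(NULL)
  per_hit <- split(ho, ho$hit)
  pooled <- NULL
  for (h in per_hit) {
    if (!all(offsets %in% h$offset)) next
    p1 <- h$cpg_pos0[match(offsets[1L], h$offset)]
    p2 <- h$cpg_pos0[match(offsets[2L], h$offset)]
    rc <- calls[calls$contig == h$contig[1L] & calls$pos0 %in% c(p1, p2) &
                  calls$state != "AMBIG", , drop = FALSE]
    if (nrow(rc) == 0L) next
    # re-key positions onto a common pair so tables pool across hits
    rc$pos0 <- ifelse(rc$pos0 == p1, 0L, 1L)
    rc$query_name <- paste(h$hit[1L], rc$query_name)
    rc$contig <- "pooled"
    pooled <- rbind(pooled, rc)
  }
  if (is.null(pooled)) return(NULL)
  comethylation_test(pooled, cpg_pair = c(0L, 1L), contig = "pooled")
}
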