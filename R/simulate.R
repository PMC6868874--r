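#' Configuration for the synthetic bisulfite-tagmentation simulator
#'
#' The generator emulates a peak-enriched directional bisulfite paired-end
#' library over a toy genome: a random background sequence seeded with CpGs
#' at a target density, non-overlapping accessibility peaks, a mixture
#' methylome (mostly-low, intermediate, mostly-high CpG classes), fragments
#' sampled much more densely inside peaks than outside, and per-base
#' bisulfite chemistry with configurable conversion efficiency and a flat
#' sequencing error.
#'
#' @param seed integer seed; the whole simulation is deterministic given it
#' @param genome_length total genome length in bp
#' @param n_contigs number of contigs (equal length)
#' @param cpg_rate target CpG density per bp
#' @param n_peaks number of peaks
#' @param peak_width_mean,peak_width_sd peak width distribution (bp)
#' @param mixture_weights probabilities of the low/intermediate/high
#'   methylation classes (must sum to 1); class beta ranges are
#'   `[0, 0.2)`, `[0.2, 0.8]`, `(0.8, 1]`
#' @param depth_in_peak,depth_background mean fragment coverage inside /
#'   outside peaks
#' @param fragment_length_mean,fragment_length_sd fragment length (normal,
#'   truncated to `[50, 1000]`)
#' @param conversion_rate probability an unmethylated C reads as T
#' @param failure_rate probability a methylated C reads as T
#' @param sequencing_error flat per-base substitution rate, applied last
#' @param read_length mate read length (bp)
#' @param rho pairwise co-methylation correlation of the Bernoulli draws of
#'   CpGs within one fragment (0 = independent), induced by a shared latent
#'   Gaussian factor
#' @param duplication_rate fraction of fragments re-emitted as PCR duplicates
#' @param plant_motif optional consensus sequence written at every peak
#'   summit on a random strand, emulating TF-bound accessibility peaks; its
#'   CpGs join the indexed methylome
#' @return a `SimulationConfig` list
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 200000L,
                              n_contigs = 1L,
                              cpg_rate = 0.02,
                              n_peaks = 50L,
                              peak_width_mean = 400,
                              peak_width_sd = 100,
                              mixture_weights = c(low = 0.7,
                                                  intermediate = 0.2,
                                                  high = 0.1),
                              depth_in_peak = 60,
                              depth_background = 2,
                              fragment_length_mean = 180,
                              fragment_length_sd = 50,
                              conversion_rate = 0.99,
                              failure_rate = 0.01,
                              sequencing_error = 0.001,
                              read_length = 50L,
                              rho = 0,
                              duplication_rate = 0,
                              plant_motif = NULL) {
  if (abs(sum(mixture_weights) - 1) > 1e-9) {
    stop("mixture weights must sum to 1")
  }
  if (conversion_rate <= 0 || conversion_rate > 1) stop("conversion_rate in (0,1]")
  if (failure_rate < 0 || failure_rate >= 1) stop("failure_rate in [0,1)")
  if (rho < 0 || rho > 1) stop("rho in [0,1]")
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_contigs = as.integer(n_contigs), cpg_rate = cpg_rate,
              n_peaks = as.integer(n_peaks),
              peak_width_mean = peak_width_mean, peak_width_sd = peak_width_sd,
              mixture_weights = mixture_weights,
              depth_in_peak = depth_in_peak,
              depth_background = depth_background,
              fragment_length_mean = fragment_length_mean,
              fragment_length_sd = fragment_length_sd,
              conversion_rate = conversion_rate, failure_rate = failure_rate,
              sequencing_error = sequencing_error,
              read_length = as.integer(read_length),
              rho = rho, duplication_rate = duplication_rate,
              plant_motif = plant_motif)
  class(cfg) <- "SimulationConfig"
  cfg
}

# beta-class ranges of the mixture methylome
.class_ranges <- list(low = c(0, 0.2), intermediate = c(0.2, 0.8),
                      high = c(0.8, 1))

#' Simulate a toy genome, peaks, and a truth methylome
#'
#' Builds a random ACGT background, plants CpG dinucleotides at the target
#' density (overlapping CGCG runs arising by chance are permitted and
#' indexed), packs non-overlapping peaks, and assigns every CpG a true
#' methylation probability drawn from its mixture class (low uniform on
#' `[0, 0.2)`, intermediate on `[0.2, 0.8]`, high on `(0.8, 1]`).
#'
#' @param config a [simulation_config()]
#' @return list with `genome` ([Genome()]), `peaks` (data.frame as from
#'   [read_narrowpeak()]) and `truth_cpg` (data.frame: `contig`, `pos0`,
#'   `class`, `true_beta`)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  clen <- config$genome_length %/% config$n_contigs
  contigs <- sprintf("chrS%d", seq_len(config$n_contigs))

  base_vecs <- lapply(contigs, function(ctg) {
    base <- sample(c("A", "C", "G", "T"), clen, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3))
    # break chance CG dinucleotides so the CpG density is set by planting
    # alone (replacing the G with A/T can never create a new CG)
    chance <- which(base[-clen] == "C" & base[-1L] == "G")
    if (length(chance) > 0L) {
      base[chance + 1L] <- sample(c("A", "T"), length(chance), replace = TRUE)
    }
    # plant CpGs at the target density
    n_cpg <- round(config$cpg_rate * clen)
    anchors <- sort(sample(seq_len(clen - 1L), n_cpg))
    # drop anchors that would abut (overwrite each other)
    keep <- c(TRUE, diff(anchors) >= 2L)
    anchors <- anchors[keep]
    base[anchors] <- "C"
    base[anchors + 1L] <- "G"
    base
  })
  names(base_vecs) <- contigs

  peaks <- simulate_peak_set(config, contigs, clen)

  # one motif instance per peak, written at the summit on a random strand,
  # emulating TF-bound accessibility peaks; motif CpGs are indexed and
  # receive mixture-truth betas like any other CpG
  if (!is.null(config$plant_motif) && nrow(peaks) > 0L) {
    consensus <- toupper(config$plant_motif)
    W <- nchar(consensus)
    for (i in seq_len(nrow(peaks))) {
      at <- peaks$start0[i] + peaks$summit_offset[i]
      at <- min(max(at, 0L), clen - W)
      inst <- if (stats::runif(1L) < 0.5) consensus else revcomp(consensus)
      base_vecs[[peaks$contig[i]]][at + seq_len(W)] <-
        strsplit(inst, "", fixed = TRUE)[[1L]]
    }
  }

  seqs <- vapply(base_vecs, paste, character(1), collapse = "")
  genome <- Genome(seqs)

  truth_cpg <- do.call(rbind, lapply(contigs, function(ctg) {
    pos <- genome$cpg_index[[ctg]]
    if (length(pos) == 0L) return(NULL)
    cls <- sample(names(config$mixture_weights), length(pos), replace = TRUE,
                  prob = config$mixture_weights)
    rng <- .class_ranges[cls]
    lo <- vapply(rng, `[`, numeric(1), 1L)
    hi <- vapply(rng, `[`, numeric(1), 2L)
    data.frame(contig = ctg, pos0 = pos, class = cls,
               true_beta = stats::runif(length(pos), lo, hi),
               stringsAsFactors = FALSE)
  }))
  rownames(truth_cpg) <- NULL
  list(genome = genome, peaks = peaks, truth_cpg = truth_cpg)
}

# non-overlapping peak packing by rejection; errors when infeasible
simulate_peak_set <- function(config, contigs, clen) {
  if (config$n_peaks == 0L) {
    return(data.frame(contig = character(0), start0 = integer(0),
                      end0 = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      summit_offset = integer(0)))
  }
  widths <- as.integer(pmax(50, round(stats::rnorm(config$n_peaks,
                                                   config$peak_width_mean,
                                                   config$peak_width_sd))))
  if (sum(widths) > 0.8 * config$genome_length) {
    stop("infeasible peak packing: total peak width exceeds 80% of the genome")
  }
  ctg_of <- sample(contigs, config$n_peaks, replace = TRUE)
  out <- vector("list", config$n_peaks)
  occupied <- stats::setNames(vector("list", length(contigs)), contigs)
  for (i in seq_len(config$n_peaks)) {
    w <- widths[i]
    ctg <- ctg_of[i]
    placed <- FALSE
    for (try in 1:200) {
      s <- sample.int(clen - w, 1L) - 1L
      e <- s + w
      occ <- occupied[[ctg]]
      clash <- FALSE
      if (!is.null(occ)) {
        clash <- any(s < occ[, 2L] & occ[, 1L] < e)
      }
      if (!clash) {
        occupied[[ctg]] <- rbind(occ, c(s, e))
        out[[i]] <- data.frame(contig = ctg, start0 = s, end0 = e,
                               stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible peak packing: could not place peak ", i)
  }
  peaks <- do.call(rbind, out)
  peaks <- peaks[order(peaks$contig, peaks$start0), , drop = FALSE]
  peaks$name <- sprintf("peak_%03d", seq_len(nrow(peaks)))
  peaks$score <- 100
  peaks$strand <- "."
  peaks$summit_offset <- (peaks$end0 - peaks$start0) %/% 2L
  rownames(peaks) <- NULL
  peaks
}

#' Simulate aligned directional bisulfite fragments
#'
#' Fragments are sampled so mean coverage is `depth_in_peak` over peak bases
#' and `depth_background` elsewhere, with OT/OB strands equiprobable. For each
#' CpG a fragment covers, one methylation state is drawn per molecule from
#' Bernoulli(true beta) — shared by both mates — with optional within-fragment
#' correlation `rho` via a common latent Gaussian factor. Read bases follow
#' directional bisulfite chemistry in forward-genome (SAM) orientation: on OT
#' molecules cytosines are read at the C, on OB at the paired G; methylated
#' CpG cytosines survive with probability `1 - failure_rate`, unmethylated
#' (and non-CpG) cytosines convert with probability `conversion_rate`. A flat
#' per-base sequencing error is applied last. Reads are emitted already
#' aligned, with correct SAM coordinates and flags.
#'
#' @param config a [simulation_config()]
#' @param genome,peaks,truth_cpg outputs of [simulate_genome()]
#' @return list with `fragments` (data.frame in the [read_alignments()]
#'   layout) and `truth_calls` (data.frame: `query_name`, `contig`, `pos0`,
#'   `methylated` — the Bernoulli draw per fragment x CpG)
#' @export
simulate_reads <- function(config, genome, peaks, truth_cpg) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  lens <- contig_lengths(genome)
  frag_rows <- list()
  truth_rows <- list()
  frag_i <- 0L

  beta_of <- stats::setNames(truth_cpg$true_beta,
                             paste(truth_cpg$contig, truth_cpg$pos0))

  # expected informative (mate-covered) bases per fragment under the
  # truncated length distribution; depths are calibrated against it so
  # depth_in_peak is realized *read* coverage, not fragment-span coverage
  e_inf <- expected_informative_bases(config)
  e_flen <- expected_fragment_length(config)

  for (ctg in names(lens)) {
    L <- lens[[ctg]]
    pk <- peaks[peaks$contig == ctg, , drop = FALSE]
    # sampling windows are peak spans padded by half a fragment so coverage
    # is flat across the whole peak rather than dented at the edges
    win <- (pk$end0 - pk$start0) + e_flen
    n_peak_frags <- if (nrow(pk) > 0L && config$depth_in_peak > 0) {
      stats::rpois(1L, config$depth_in_peak * sum(win) / e_inf)
    } else 0L
    n_bg_frags <- if (config$depth_background > 0) {
      stats::rpois(1L, config$depth_background * L / e_inf)
    } else 0L
    n <- n_peak_frags + n_bg_frags
    if (n == 0L) next

    flen <- round(stats::rnorm(n, config$fragment_length_mean,
                               config$fragment_length_sd))
    flen <- pmin(pmax(flen, 50L), 1000L)
    # peak fragments: center in the padded peak window; background: uniform
    origin <- c(if (n_peak_frags > 0L)
                  sample(pk$name, n_peak_frags, replace = TRUE,
                         prob = win) else character(0),
                rep("background", n_bg_frags))
    centers <- integer(n)
    if (n_peak_frags > 0L) {
      ip <- seq_len(n_peak_frags)
      idx <- match(origin[ip], pk$name)
      # window shrunk one base per side so every fragment overlaps its peak
      half <- flen[ip] / 2
      centers[ip] <- round(stats::runif(n_peak_frags,
                                        pk$start0[idx] - half + 1,
                                        pk$end0[idx] + half - 1))
    }
    if (n_bg_frags > 0L) {
      centers[n_peak_frags + seq_len(n_bg_frags)] <- sample.int(L, n_bg_frags) - 1L
    }
    start0 <- pmax(0L, centers - flen %/% 2L)
    end0 <- pmin(L, start0 + flen)
    start0 <- pmax(0L, pmin(start0, end0 - 50L))
    strand <- sample(c("OT", "OB"), n, replace = TRUE)

    seq_ctg <- genome$sequences[[ctg]]
    cpg_pos <- genome$cpg_index[[ctg]]

    qn <- sprintf("frag%07d", frag_i + seq_len(n))
    frag_i <- frag_i + n
    rl <- pmin(config$read_length, end0 - start0)
    seq1 <- character(n); seq2 <- character(n)
    t_qn <- vector("list", n); t_pos <- vector("list", n)
    t_meth <- vector("list", n)
    for (i in seq_len(n)) {
      s <- start0[i]; e <- end0[i]
      cov_cpg <- cpg_pos[cpg_pos >= s & cpg_pos < e]
      meth <- logical(0)
      if (length(cov_cpg) > 0L) {
        b <- beta_of[paste(ctg, cov_cpg)]
        meth <- draw_correlated_bernoulli(b, config$rho)
        t_qn[[i]] <- rep(qn[i], length(cov_cpg))
        t_pos[[i]] <- cov_cpg
        t_meth[[i]] <- meth
      }
      seq1[i] <- bisulfite_read(seq_ctg, s, s + rl[i], strand[i],
                                cov_cpg, meth, config)
      seq2[i] <- bisulfite_read(seq_ctg, e - rl[i], e, strand[i],
                                cov_cpg, meth, config)
    }
    frag_rows[[ctg]] <- data.frame(
      query_name = qn, contig = ctg, start0 = start0, end0 = end0,
      bisulfite_strand = strand, mapq = 42L,
      seq1 = seq1, qual1 = strrep("I", rl), pos1 = start0,
      seq2 = seq2, qual2 = strrep("I", rl), pos2 = end0 - rl,
      origin = origin, stringsAsFactors = FALSE)
    t_qn <- unlist(t_qn, use.names = FALSE)
    if (is.null(t_qn)) t_qn <- character(0)
    truth_rows[[ctg]] <- data.frame(
      query_name = t_qn,
      contig = rep(ctg, length(t_qn)),
      pos0 = as.integer(unlist(t_pos, use.names = FALSE)),
      methylated = as.logical(unlist(t_meth, use.names = FALSE)),
      stringsAsFactors = FALSE)
  }
  fragments <- rbind_rows(frag_rows)
  truth_calls <- rbind_rows(truth_rows)
  if (is.null(fragments)) stop("no fragments simulated; raise depth")
  if (is.null(truth_calls) || nrow(truth_calls) == 0L) {
    truth_calls <- data.frame(query_name = character(0), contig = character(0),
                              pos0 = integer(0), methylated = logical(0))
  }
  if (config$duplication_rate > 0 && nrow(fragments) > 0L) {
    dup <- which(stats::runif(nrow(fragments)) < config$duplication_rate)
    if (length(dup) > 0L) {
      dups <- fragments[dup, , drop = FALSE]
      dups$query_name <- paste0(dups$query_name, "dup")
      fragments <- rbind(fragments, dups)
    }
  }
  list(fragments = fragments, truth_calls = truth_calls)
}

# discretized truncated-normal fragment length distribution on [50, 1000]
fragment_length_pmf <- function(config) {
  l <- 50:1000
  p <- stats::pnorm(l + 0.5, config$fragment_length_mean,
                    config$fragment_length_sd) -
    stats::pnorm(l - 0.5, config$fragment_length_mean,
                 config$fragment_length_sd)
  p[1L] <- stats::pnorm(50.5, config$fragment_length_mean,
                        config$fragment_length_sd)
  p[length(p)] <- stats::pnorm(999.5, config$fragment_length_mean,
                               config$fragment_length_sd, lower.tail = FALSE)
  list(length = l, p = p / sum(p))
}

expected_fragment_length <- function(config) {
  pmf <- fragment_length_pmf(config)
  sum(pmf$length * pmf$p)
}

# expected bases covered by the two mates of one fragment
expected_informative_bases <- function(config) {
  pmf <- fragment_length_pmf(config)
  sum(pmin(pmf$length, 2L * config$read_length) * pmf$p)
}

# Correlated Bernoulli draws via a single latent factor: z_i shares loading
# sqrt(rho) on a common standard normal, so every pair has correlation rho on
# the latent scale; marginal P(methylated) stays exactly beta_i.
draw_correlated_bernoulli <- function(beta, rho) {
  k <- length(beta)
  if (rho == 0 || k == 1L) {
    return(stats::runif(k) < beta)
  }
  f <- stats::rnorm(1L)
  z <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(k)
  z < stats::qnorm(beta)
}

# One mate in forward-genome orientation over [m_start, m_end).
# cov_cpg/meth: per-molecule CpG states (0-based C positions, fragment-wide).
bisulfite_read <- function(seq_ctg, m_start, m_end, strand, cov_cpg, meth,
                           config) {
  bases <- strsplit(substr(seq_ctg, m_start + 1L, m_end), "", fixed = TRUE)[[1L]]
  n <- length(bases)
  pos <- m_start + seq_len(n) - 1L
  if (strand == "OT") {
    is_c <- bases == "C"
    informative <- match(pos, cov_cpg)        # CpG C read on OT
    conv_to <- "T"
  } else {
    is_c <- bases == "G"
    informative <- match(pos, cov_cpg + 1L)   # CpG G read on OB
    conv_to <- "A"
  }
  cpg_here <- is_c & !is.na(informative)
  u <- stats::runif(n)
  # methylated CpG cytosine: retained unless bisulfite failure
  sel <- cpg_here & meth[informative]
  bases[sel & (u < config$failure_rate)] <- conv_to
  # unmethylated CpG cytosine: converted at the conversion rate
  sel <- cpg_here & !meth[informative]
  bases[sel & (u < config$conversion_rate)] <- conv_to
  # non-CpG cytosine on the read strand: effectively unmethylated
  sel <- is_c & !cpg_here
  bases[sel & (u < config$conversion_rate)] <- conv_to
  if (config$sequencing_error > 0) {
    err <- stats::runif(n) < config$sequencing_error
    if (any(err)) {
      alt <- c("A", "C", "G", "T")
      bases[err] <- vapply(bases[err], function(b) {
        sample(setdiff(alt, b), 1L)
      }, character(1))
    }
  }
  paste(bases, collapse = "")
}

#' Run the full simulation and write its files
#'
#' Convenience wrapper: [simulate_genome()] + [simulate_reads()], writing
#' `ref.fa`, `peaks.narrowPeak`, `reads.sam`, `truth_cpg.tsv` and
#' `truth_frag.tsv` into `outdir`.
#'
#' @param config a [simulation_config()]
#' @param outdir output directory (created if needed)
#' @return (invisibly) list with `genome`, `peaks`, `truth_cpg`, `fragments`,
#'   `truth_calls` and the written `paths`
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(config)
  rd <- simulate_reads(config, gen$genome, gen$peaks, gen$truth_cpg)
  paths <- c(ref = file.path(outdir, "ref.fa"),
             peaks = file.path(outdir, "peaks.narrowPeak"),
             reads = file.path(outdir, "reads.sam"),
             truth_cpg = file.path(outdir, "truth_cpg.tsv"),
             truth_frag = file.path(outdir, "truth_frag.tsv"))
  write_fasta(gen$genome, paths[["ref"]])
  write_narrowpeak(gen$peaks, paths[["peaks"]])
  write_sam(rd$fragments, paths[["reads"]], gen$genome)
  write_tsv_commented(gen$truth_cpg, paths[["truth_cpg"]],
                      comment = sprintf("seed=%d", config$seed))
  write_tsv_commented(rd$truth_calls, paths[["truth_frag"]],
                      comment = sprintf("seed=%d", config$seed))
  invisible(c(gen, rd, list(paths = paths)))
}

# TSV with a '#'-prefixed header comment line
write_tsv_commented <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate joint methylation calls at a designated CpG pair
#'
#' Direct generator for fragments that cover two CpGs of interest (for
#' example the two CpG-capable positions of a TF motif): each fragment gets
#' one Bernoulli draw per CpG with latent-Gaussian correlation `rho`, in the
#' read-call layout consumed by [comethylation_test()].
#'
#' @param n_fragments number of fragments covering both CpGs
#' @param beta1,beta2 true methylation probabilities of the two CpGs
#' @param rho latent correlation (0 = independent)
#' @param cpg_pair 0-based coordinates of the two CpGs
#' @param contig contig name
#' @return data.frame of read calls: `query_name`, `contig`, `pos0`, `state`
#' @export
simulate_comethylation_calls <- function(n_fragments, beta1, beta2, rho = 0,
                                         cpg_pair = c(100L, 110L),
                                         contig = "chrS1") {
  z1 <- stats::rnorm(n_fragments)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_fragments)
  m1 <- z1 < stats::qnorm(beta1)
  m2 <- z2 < stats::qnorm(beta2)
  qn <- sprintf("pairfrag%06d", seq_len(n_fragments))
  data.frame(
    query_name = rep(qn, each = 2L),
    contig = contig,
    pos0 = rep(as.integer(cpg_pair), times = n_fragments),
    state = ifelse(as.vector(rbind(m1, m2)), "METH", "UNMETH"),
    stringsAsFactors = FALSE)
}
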