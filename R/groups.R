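#' Thresholds for the methylation-by-coverage CpG grouping
#'
#' The four-group classification of CpGs inside accessibility peaks splits on
#' methylation (low < 20%, intermediate 20-80% inclusive, high > 80%) and
#' informative coverage (low 5-50 reads inclusive, high > 50 reads). Sites
#' below `cov_min` reads are excluded outright. Boundary values land in the
#' inclusive interval their name states.
#'
#' @param meth_low,meth_high methylation split points (fractions)
#' @param cov_min,cov_high coverage split points (reads)
#' @return a `GroupingThresholds` list
#' @export
grouping_thresholds <- function(meth_low = 0.20, meth_high = 0.80,
                                cov_min = 5L, cov_high = 50L) {
  stopifnot(meth_low > 0, meth_low < meth_high, meth_high < 1,
            cov_min > 0, cov_min <= cov_high)
  structure(list(meth_low = meth_low, meth_high = meth_high,
                 cov_min = as.integer(cov_min),
                 cov_high = as.integer(cov_high)),
            class = "GroupingThresholds")
}

#' Assign CpG sites to methylation/coverage groups
#'
#' Vectorized over sites. Labels: `G1` low methylation + high coverage, `G2`
#' low methylation + low coverage, `G3` intermediate methylation + low
#' coverage, `G4` high methylation + low coverage, `UNGROUPED` intermediate
#' or high methylation with high coverage (a combination depleted in real
#' accessibility data), `EXCLUDED` below the minimum coverage.
#'
#' @param sites data.frame with `beta` and `coverage`
#' @param thresholds a [grouping_thresholds()]
#' @return character vector of labels, one per site
#' @export
assign_group <- function(sites, thresholds = grouping_thresholds()) {
  t <- thresholds
  beta <- sites$beta
  cov <- sites$coverage
  low <- beta < t$meth_low
  high <- beta > t$meth_high
  hicov <- cov > t$cov_high
  label <- rep("UNGROUPED", length(beta))
  label[low & hicov] <- "G1"
  label[low & !hicov] <- "G2"
  label[!low & !high & !hicov] <- "G3"
  label[high & !hicov] <- "G4"
  label[cov < t$cov_min] <- "EXCLUDED"
  label
}

#' Methylation bounds of a group label
#'
#' `G1`/`G2`: `[0, meth_low)`; `G3`: `[meth_low, meth_high]` (upper bound
#' open for the probability integral); `G4`: `(meth_high, 1]`. Bounds are
#' returned as the `(C_l, C_h)` pair used by
#' [cluster_membership_probability()].
#'
#' @param label group label
#' @param thresholds a [grouping_thresholds()]
#' @return numeric length-2 vector `c(C_l, C_h)`
#' @export
group_bounds <- function(label, thresholds = grouping_thresholds()) {
  t <- thresholds
  switch(label,
         G1 = ,
         G2 = c(0, t$meth_low),
         G3 = c(t$meth_low, t$meth_high),
         G4 = c(t$meth_high, 1),
         stop("no methylation bounds for label ", label))
}

#' Probability that a CpG's beta lies within its group's bounds
#'
#' Models the observed beta (a sampling mean over `n` reads) as normal with
#' mean `b` and variance `b(1-b)/(n-1)`, and returns
#' `P(b < C_h) - P(b < C_l)` under that normal. When the variance degenerates
#' to zero (`b` of exactly 0 or 1), the probability is 1 if `b` lies inside
#' `[C_l, C_h)` and 0 otherwise.
#'
#' @param b observed beta (mean methylation)
#' @param n total informative reads (>= 2)
#' @param C_l,C_h lower / upper methylation bounds of the assigned group
#' @return probability in `[0, 1]`; vectorized over `b`/`n`
#' @export
cluster_membership_probability <- function(b, n, C_l, C_h) {
  if (any(n < 2)) stop("n must be >= 2 for the variance b(1-b)/(n-1)")
  if (any(C_l >= C_h)) stop("C_l must be < C_h")
  s <- sqrt(b * (1 - b) / (n - 1))
  p <- ifelse(s > 0,
              stats::pnorm((C_h - b) / s) - stats::pnorm((C_l - b) / s),
              as.numeric(b >= C_l & b < C_h))
  p
}

#' Group counts, distributions and membership probabilities
#'
#' Assigns every site a label, attaches the cluster-membership probability
#' for grouped sites (bounds from the site's own group), and summarises
#' counts and beta/coverage distributions per label.
#'
#' @param sites data.frame of (filtered) CpG sites
#' @param thresholds a [grouping_thresholds()]
#' @return list with `sites` (input + `label`, `membership_probability`) and
#'   `summary` (per-label count, median beta, median coverage, median
#'   membership probability, fraction of grouped sites)
#' @export
group_summary <- function(sites, thresholds = grouping_thresholds()) {
  label <- assign_group(sites, thresholds)
  prob <- rep(NA_real_, nrow(sites))
  for (g in c("G1", "G2", "G3", "G4")) {
    sel <- label == g & sites$coverage >= 2L
    if (!any(sel)) next
    bd <- group_bounds(g, thresholds)
    prob[sel] <- cluster_membership_probability(sites$beta[sel],
                                                sites$coverage[sel],
                                                bd[1L], bd[2L])
  }
  out_sites <- sites
  out_sites$label <- label
  out_sites$membership_probability <- prob
  lev <- c("G1", "G2", "G3", "G4", "UNGROUPED", "EXCLUDED")
  fl <- factor(label, levels = lev)
  n_grouped <- sum(label %in% c("G1", "G2", "G3", "G4"))
  med <- function(x) vapply(split(x, fl), function(v) {
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  summary <- data.frame(
    label = lev,
    count = as.integer(table(fl)),
    median_beta = unname(med(sites$beta)),
    median_coverage = unname(med(as.numeric(sites$coverage))),
    median_membership_probability = unname(med(prob)),
    fraction_of_grouped = ifelse(lev %in% c("G1", "G2", "G3", "G4") &
                                   n_grouped > 0L,
                                 as.integer(table(fl)) / n_grouped, NA_real_),
    stringsAsFactors = FALSE)
  list(sites = out_sites, summary = summary)
}
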