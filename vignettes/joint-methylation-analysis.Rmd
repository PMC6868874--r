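---
title: "Joint methylation and occupancy analysis from bisulfite tagmentation libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint methylation and occupancy analysis from bisulfite tagmentation libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Tagmentation assays that bisulfite-convert the library before amplification
read two signals from the same DNA molecule: where the genome is accessible
(or bound by a transcription factor), and whether its CpGs are methylated.
`tagmeth` implements the downstream analysis of such libraries: methylation
calling from aligned directional bisulfite fragments, integration with peak
calls, a methylation-by-coverage classification of peak CpGs with a
confidence model, motif scanning with exact score-distribution p-values, and
a per-molecule co-methylation test. A synthetic read simulator provides
ground truth for validation; the numbered scripts under `analysis/` walk the
full workflow on simulated data.

## Methylation calling

All coordinates are 0-based half-open, and a CpG is always addressed by its
forward-strand C position. In a directional library every fragment descends
from the original top (OT) or original bottom (OB) strand; in forward-genome
(SAM) orientation the informative base is the C of the CpG on OT molecules
(`C` methylated, `T` unmethylated) and the paired G on OB molecules (`G`
methylated, `A` unmethylated). Any other base, or one below the base-quality
floor (default Q20), is ambiguous and drops out of both counts.

Counting is per fragment, not per read: when mates overlap a CpG the call
with the higher base quality wins (ties to read 1), so one molecule never
contributes twice. Fragments are ingested with `read_alignments()`, which
keeps primary proper pairs, drops fragments with mapping quality below 30,
and collapses coordinate duplicates. The duplicate key includes the
bisulfite strand: an OT and an OB fragment with identical coordinates are
distinct molecules under directional chemistry and are both kept.

Per-CpG evidence from the two strands is pooled by default
(`merge_strands = TRUE`): counts are summed and beta (`count_meth /
coverage`) recomputed, never averaged, so coverage weighting stays exact.
CpG methylation is near-symmetric in bulk vertebrate data and pooling
maximizes the coverage the downstream grouping keys on; `merge_strands =
FALSE` preserves per-strand sites for asymmetry checks. Only CpG-context
cytosines are considered anywhere; there is no CHG/CHH output.

Downstream analyses use `filter_sites()`: only CpGs inside a peak and
covered by at least five informative reads are kept, because methylation
estimates outside enriched regions are shallow and unreliable.

## The simulator

`simulation_config()` defines the study conditions; its defaults are what
the tests and the acceptance script run:

* genome: one 200 kb contig with CpGs planted at 0.02/bp (chance CG
  dinucleotides in the random background are broken first, so density is
  controlled by planting alone; overlapping CGCG runs remain possible);
* 50 non-overlapping peaks, width 400 ± 100 bp;
* a mixture methylome: each CpG's true beta is drawn uniformly within its
  class range — mostly-low `[0, 0.2)` with weight 0.7, intermediate
  `[0.2, 0.8]` with 0.2, mostly-high `(0.8, 1]` with 0.1;
* fragments of 180 ± 50 bp (truncated to `[50, 1000]`), 50-bp mates, OT/OB
  equiprobable; per-molecule CpG states drawn once and shared by both mates;
* chemistry: unmethylated C reads as T with probability 0.99 (conversion),
  methylated C as T with probability 0.01 (failure), plus a flat 0.001
  per-base substitution error applied last;
* depth: 60x inside peaks, 2x outside. Depth is calibrated to *informative
  read* coverage — the bases actually under a mate — not fragment-span
  coverage: with 180-bp fragments and 50-bp mates only ~100 bp of each
  fragment is read, and fragment counts are scaled by the expected
  mate-covered bases under the truncated length distribution. Peak
  fragments are centered in a window padded by half a fragment length so
  coverage is flat across the peak rather than dented at its edges.

Reads are emitted already aligned, with SAM flags (99/147 for OT, 83/163
for OB) matching how `read_alignments()` infers the bisulfite strand;
alignment itself is out of scope. An optional `rho` correlates the
methylation draws of CpGs within one fragment through a shared latent
Gaussian factor with loading `sqrt(rho)`, giving every within-fragment pair
latent correlation `rho` while preserving each CpG's marginal beta — this
exercises the co-methylation test's power. An optional `plant_motif` writes
a consensus sequence at every peak summit on a random strand, emulating
TF-bound accessibility peaks, so motif-position analyses have real targets.

What the simulator does not emulate: indels and soft-clipping (all CIGARs
are a single match run), quality-score structure (flat Q40 with a flat error
rate), GC or Tn5 insertion bias, fragment-level methylation haplotypes
beyond the single-factor correlation, copy-number structure, and non-CpG
methylation. Tests passing on these data therefore validate the arithmetic
and the statistical calibration of the pipeline, not its robustness to
alignment artifacts in real libraries.

## CpG groups and the membership probability

Peak CpGs are classified on two axes read literally from the grouping's
definition: methylation low (< 20%), intermediate (20–80%, both ends
inclusive), high (> 80%); coverage low (5–50 reads, inclusive) or high
(> 50 reads). G1 = low/high-coverage, G2 = low/low, G3 = intermediate/low,
G4 = high/low; sites under 5 reads are excluded, and intermediate-or-high
methylation at high coverage — a combination depleted in real accessibility
data — is reported as UNGROUPED rather than forced into a group.

Confidence in an assignment uses a normal model for the sampling mean: beta
is treated as Normal with mean `b` and variance `b(1 − b)/(n − 1)`, where
`n` is the site's total informative reads, and the membership probability is
`P(b < C_h) − P(b < C_l)` for the group's methylation bounds. The CDF is the
standard erf-based `pnorm`; no Monte Carlo sits in the production path. At
`b` of exactly 0 or 1 the variance degenerates and the probability is the
indicator of `b ∈ [C_l, C_h)`. The model needs `n ≥ 2`.

The normal approximation has a floor: against exact binomial resampling of
`binomial(n−1, b)/(n−1)` the probability differs by several percentage
points at `n = 10` for every interior `b` (discreteness plus skew), and the
gap only falls below 0.03 from roughly `n = 50` upward. The test suite
asserts exactly that — the gap shrinks with `n` and is within 0.03 at
`n ∈ {50, 200}` — rather than pretending the approximation is uniformly
accurate at very low counts. Coverage enters the model only through `n`;
the bounds are one-dimensional in beta.

## Peak summaries and QC

`peak_mean_methylation()` averages site betas per peak unweighted (each CpG
one vote). Cross-assay comparison labels each shared peak into a 2x2
quadrant at a threshold of 0.5 per axis; values at the threshold count as
"high". The threshold is configurable — a single split per axis is the only
reading consistent with four corner counts. QC operations are the peak-set
Jaccard index (intersection over union of merged intervals), the Pearson
correlation of binned fragment-midpoint counts (default 10-kb bins;
zero-variance vectors are an error rather than a silent NA), and the
fragment-length histogram capped at 1000 bp.

`annotate_regions()` labels regions promoter > intragenic > intergenic,
with the promoter a ±3 kb window around the TSS. The source material's
"distal from promoter > 1 kb" intergenic phrasing conflicts with a ±3 kb
promoter window (anything non-promoter is already ≥ 3 kb from the TSS
unless it overlaps the window edge); rather than guess the intent, the
distance test is kept as a separate `promoter_distal` flag
(`intergenic_min_dist`, default 1 kb) and the three labels stay exhaustive.

## Motif analysis

`pwm_from_counts()` builds column-normalized probabilities with a
pseudocount (default 1) and base-2 log-odds against a configurable
background (default uniform — scanner backgrounds are rarely reported, and
uniform keeps scores interpretable as bits). The scanner is implemented
here, not wrapped: every window on both strands is scored by summing
per-column log-odds, windows containing non-ACGT bases are skipped, and
minus-strand hits are windows whose reverse complement matches.

The score threshold comes from the exact distribution of the score under
the background model, computed by position-wise convolution on a
discretized grid (0.01 bits per bin): the threshold is the smallest grid
score whose upper-tail probability is at most the requested p-value
(default 1e-4). Discretization error is bounded by half a bin per column; a
p-value of 1 admits every window. Tests verify the scanner against
brute-force window enumeration and the threshold against enumeration of all
4^W sequences for W ≤ 6.

`hit_cpg_offsets()` reports, per hit, the 1-based motif columns whose
genomic sequence carries a CpG, mapped back to the forward-strand C — on a
minus hit a CpG at forward offset `k` appears at motif position `W − k`.
`position_methylation()` collects filtered-site betas per requested offset
(defaults 2 and 12, the CpG-capable columns of the 19-bp occupancy motif
used in the analysis scripts) and compares offsets with a rank-sum test
(normal approximation with tie correction, via `wilcox.test`); a CpG
reached by several hits counts once per (hit, offset) unless `unique_cpg`
collapses to the best-scoring hit. A paired variant
(`paired_methylation_test()`) compares the same CpGs across two assays.

`comethylation_test()` counts the four joint states (MM, MU, UM, UU) of
fragments informative at both CpGs of a pair, takes expected counts from
the table's own marginals under independence, and reports the Pearson
chi-square with one degree of freedom plus the observed and expected
doubly-methylated fractions. Fewer than two informative fragments, or a
marginal of exactly 0 or 1, leaves the statistic undefined (NA) rather than
infinite. When pooling across hits (`run_pipeline()` does this for the two
requested offsets), fragments are re-keyed per hit so the same molecule
never enters twice. The repository ships a synthetic 19-bp CTCF-like count
matrix (`inst/extdata/ctcf_like_synthetic.pfm`, labelled synthetic — it is
not a database matrix) whose only CpG-capable columns are 2–3 and 12–13.

## Numerical and interface choices

* Boundary conventions: methylation 20% and 80% fall in the intermediate
  group; coverage 5 and 50 fall in the low-coverage groups; a site at a
  peak's end coordinate is outside it (half-open intervals); quadrant ties
  go to "high".
* Bismark-style coverage files are 1-based start==end and are converted at
  ingest; beta is recomputed from counts, the percentage column being
  advisory only. Destranding folds a G-position record onto the C at
  position − 1 using the genome's CpG index. bedGraph is accepted
  read-only, with counts unknown.
* The simulator treats non-CpG cytosines as unmethylated (converted at the
  conversion rate); the caller never reads them, so this choice only
  affects read realism.
* Problem sizes: the test suite and the acceptance script run the default
  200-kb/50-peak genome for pipeline-level checks (a few tens of thousands
  of fragments), 20-kb genomes for unit-level properties, 20 random 2-kb
  sequences for scanner enumeration, and 500 replicates of 500 fragment
  pairs for co-methylation calibration — sizes chosen so every property is
  measurable with comfortable statistical margins on a single core.

## Known limitations

* Ungapped alignments only: CIGARs other than a single match run are not
  placed base-by-base.
* The membership probability is a normal approximation; see above for its
  behavior at low read counts.
* The co-methylation chi-square relies on the large-sample approximation;
  with expected cell counts below ~5 its null calibration degrades (the
  worked examples keep expected counts near that boundary deliberately, as
  checks of the arithmetic rather than of asymptotics).
* The quadrant threshold (0.5) and the motif background (uniform) are
  conventions, not estimates; both are parameters.
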