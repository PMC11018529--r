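---
title: "Methods: homoeolog bias, expression shift, co-expression and fractionation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog bias, expression shift, co-expression and fractionation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgenomeBias)
```

This vignette explains the models and procedures the package implements,
the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical choices made where a
design was genuinely open. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The problem

Allopolyploids carry two or more parental subgenomes whose corresponding
gene copies — homoeologs — can diverge in expression. The package
quantifies that divergence for homoeologous groups with exactly one
retained copy per subgenome (1:1 pairs in tetraploids, 1:1:1 triads in
hexaploids), and tracks the complementary retention signal (biased
fractionation: unequal post-polyploidy gene loss between subgenomes).

## Preprocessing

Raw counts are converted to TPM by dividing each gene's count by its
length in kilobases and scaling each sample to one million; columns sum
to 10⁶ exactly, and the transform is invariant to rescaling any sample's
sequencing depth. Expressed genes are those with TPM ≥ 1 (inclusive) in
at least two samples; the filter runs on the replicate-level matrix,
before averaging, and is idempotent. Replicates are averaged
arithmetically within tissue; pattern analyses use log2(TPM + 1), which
maps 0 to 0 and compresses large values while preserving small ones.

An optional quality step flags a replicate whose Pearson correlation to
the centroid of its tissue-mates falls below 0.8. This is a declared,
configurable stand-in for visual clustering checks of replicate
consistency; there is no field-standard numeric rule.

## Triad bias classification

For an expressed triad (averaged TPMs summing to more than 0.5 — a
strict inequality; the threshold excludes triads whose classification
would rest on noise around zero), the relative-expression vector lies on
the 2-simplex and is assigned to the nearest of seven ideal points:
balanced (1/3, 1/3, 1/3), three single-homoeolog-dominant vertices, and
three single-homoeolog-suppressed edge midpoints (0 at the silenced
copy, 1/2 elsewhere). The wheat-style scheme is sometimes described as
"six categories" with balanced treated separately; the package
implements all seven points as the default and offers a biased-only
six-point mode (`include_balanced = FALSE`).

Distances are Euclidean. Ties (distances equal within 1e-12) are
resolved by a fixed category order — balanced, then dominants, then
suppresseds, alphabetical within tier — and flagged. The tolerance
matters: a vector lying exactly between two ideal points differs in
floating point by ~1e-16 in squared distance, and without the tolerance
the winner would depend on rounding rather than on the declared order.

Pair-level bias uses log2((TPM_x + 0.01)/(TPM_y + 0.01)); the 0.01
pseudocount and the hexaploid deviation constant 0.33 are configuration
values defaulting to the conventional printed numbers. Note that
0.33 ≠ 1/3 exactly, so a perfectly balanced triad has a small positive
deviation of log2((1/3)/0.33) ≈ 0.0145.

Replicate-level differential expression between homoeologs is a
two-sided Welch t-test on log2(TPM+1) replicate values with
Benjamini–Hochberg adjustment across all groups tested within one
tissue and label pair, calling a homoeolog up-regulated when adjusted
p < 0.05 and the |log2 fold change| of replicate-mean TPMs (with the
same 0.01 pseudocount) is at least 1. This self-contained criterion
stands in for count-model engines; the test function is pluggable
(`test_fun`), so a count-based GLM can be substituted without changing
the counting logic. BH adjustment is applied within tissue because
cross-tissue pooling would couple unrelated hypothesis families.

## Expression shift

Homoeolog tissue profiles are clustered into k = 10 groups by
average-linkage agglomeration. The dissimilarity is 1 − Pearson
correlation between profiles: pattern similarity, not level similarity,
is what "same expression pattern" means here; Euclidean distance on the
log scale is available as an alternative (`method = "euclidean"`).
Constant (zero-variance) profiles have undefined correlation; they get
distance 0 to identical profiles and 1 to everything else. Profiles are
sorted by gene id before clustering, so the result is invariant to input
order. A group is *shifted* when its members do not all share a cluster;
the shifted fraction is monotone non-decreasing in k, so comparisons are
only meaningful at fixed k.

The subsampling mode redraws `n_target` groups without replacement
`n_reps` times, reclusters each draw, and reports the distribution of
shifted fractions — the device that puts a large pair cohort and a
smaller triad cohort on equal footing. It is seeded; at
`n_target = `all groups, every draw reproduces the full-data fraction
exactly.

## Co-expression

The network is a deliberately lightweight re-specification of weighted
co-expression methodology, built for determinism and testability rather
than feature parity with the full toolchain:

* **bicor** — biweight midcorrelation with u = (x − median)/(9·MAD)
  (unscaled MAD), weights (1 − u²)²·1[|u| < 1]. The `max_p_outliers`
  cap (default 0.05) rescales each side of u so at most that fraction of
  observations per tail receives zero weight. `robust = FALSE` gives
  plain Pearson for oracle comparisons.
* **Soft power** — smallest β in 1..30 whose signed scale-free fit
  (R² of log-frequency on log-connectivity over 10 bins, negated for
  positive slopes) reaches 0.9; if none qualifies, the best-fitting
  power is returned with a warning. Latent-factor simulations are not
  scale-free, so pipelines on planted-module data typically pass an
  explicit moderate power (6) instead of scanning.
* **Adjacency** — signed hybrid: cor^β for positive correlations, 0
  otherwise, zero diagonal.
* **TOM** — unsigned: (Σ_u a_iu·a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij),
  unit diagonal, symmetrized exactly.
* **Modules** — average-linkage on 1 − TOM with a static cut at 0.99
  (a static cut replaces dynamic tree cutting: deterministic and
  sufficient for the subgenome statistics this package targets).
  Clusters under 30 genes are unassigned (label 0). Modules whose
  eigengenes correlate above 1 − 0.15 merge iteratively until stable;
  final labels are ordered by decreasing size.
* **Eigengenes and hubs** — module eigengene = first principal component
  of the standardized module submatrix, oriented to correlate positively
  with members on average, unit variance. KME is a gene's correlation
  with its own module's eigengene; KME > 0.9 defines hubs.
* **Neighbor composition** — each gene's k = 100 strongest partners by
  edge weight (TOM by default; the adjacency is a config alternative),
  ties broken by descending weight then ascending gene id, counted as
  intra- versus inter-subgenome with a per-label breakdown.

Everything runs single-block in memory: the correlation, adjacency and
TOM matrices are dense n × n doubles, so memory is O(n²) — fine for the
10³–10⁴-gene analyses this package targets, not for whole-transcriptome
networks.

## Fractionation

Retention tracks record 0/1 presence per subgenome along an ordered
reference gene list. Windows are 100 genes (the conventional
fractionation-bias window), stride 10 by default (the stride is a free
parameter pinned in configuration: it changes the number of windows but
not medians materially; stride 1 and non-overlapping windows are both
supported), 0-based and half-open, never spanning reference-chromosome
boundaries, trailing partial windows dropped. Subgenome pairs are
compared by a two-sided Wilcoxon rank-sum test on window fractions
(normal approximation; window fractions are heavily tied), reporting
sample sizes, medians and direction; identical constant samples are
degenerate and reported with p = 1 and a note. The copy-ratio census
classifies each group by its copy-count signature sorted in decreasing
order and reports percentages summing to 100.

## Synthetic data: what it emulates, and what it does not

The generators' defaults are the study conditions the analysis assumes:
five tissues (leaf blade, leaf sheath, shoot, root, rhizome) × three
biological replicates; 1,157 triads at the hexaploid scale; a planted
category mixture of 78% balanced, 2% per dominant and 16/3% per
suppressed category (echoing the magnitudes reported for hexaploid
triad cohorts: a large balanced majority, ~6% dominant, ~16%
suppressed); dominance fold 8 (a strong, unambiguous planted signal —
relative vector (0.8, 0.1, 0.1), nearer its dominant vertex than any
other ideal point); base mean 50 TPM; negative-binomial dispersion 0.05
(moderate bulk-RNA-seq replicate noise; variance = μ + φμ², φ → 0
recovers Poisson); library-size CV 0.1; gene lengths uniform on
500–5000 bp and *shared within a group*, so homoeologs are
length-matched while the TPM length correction still matters across
groups. Counts are generated on the count scale and converted to TPM
downstream, so the TPM pathway itself is exercised. Category counts are
allocated exactly (largest remainder) and shuffled, so zero-noise runs
reproduce planted proportions exactly. Each simulator seeds a private
RNG stream (fixed offsets from the master seed) and restores the
caller's RNG state, so adding one simulator call never perturbs
another's draws.

Module simulations are single-latent-factor blocks: gene = loading ×
latent + Gaussian noise, loadings uniform on 0.4–1, top-decile loadings
planted as hubs with subgenome labels drawn from the hub weights.
Retention simulations lose each reference gene independently per
subgenome.

None of this reproduces real data's length-dependent counting noise,
correlated tissue effects between homoeologs, isoform structure,
mapping bias between subgenomes, or spatially autocorrelated gene loss.
Passing tests therefore demonstrate that the implementation computes
its statistics correctly and recovers planted structure under the
assumed noise model — not that the biological conclusions of any
particular dataset would be reproduced.

## Problem sizes and determinism

The test suite and acceptance script run at deliberate desk scale:
1,157 triads × 5 tissues × 3 replicates for category recovery, 400
pairs for shift recovery, 200 genes for network recovery, 20-gene
instances for brute-force oracle comparisons, 10,000 reference genes
for retention. Headline numbers from full-scale studies (hundreds of
RNA-seq samples) are not reproducible from synthetic data and are not
asserted anywhere; the package's claims are property-based.

All pipelines are deterministic given their inputs and seeds: matrix
operations are ordered, ties have declared resolutions (lexicographic
gene ids), and every output writer emits the same bytes on rerun —
asserted in the test suite by checksumming twin runs.

## Known limitations

* The DE criterion is TPM-based (Welch t), not a count-model GLM;
  at very low counts its power differs from count-based engines.
* The static tree cut can split a diffuse module that dynamic cutting
  would keep; min-size and cut-height interact, and modules below 30
  genes are never reported.
* The scale-free fit index is bin-sensitive for small networks
  (< ~50 genes).
* Correlation-distance clustering ignores expression level entirely;
  two homoeologs at 10× different levels with proportional tissue
  patterns are "not shifted".
* Wilcoxon p-values on overlapping windows treat windows as independent
  observations; with stride < window, neighboring windows share genes
  and the effective sample size is smaller than n.
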