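---
title: "Methods and design notes for methlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for methlineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
pipeline, the parameters that matter with their defaults and rationale,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The measurement model

Micro-scale whole-genome bisulfite sequencing of sorted cell pools yields,
per sample and CpG, a methylated read count `m` out of `n` total reads.
The CpG-level methylation level is `m/n`; because individual libraries are
sequenced shallowly (well below 1x per CpG), all inference happens at the
level of genomic regions.

**Region aggregation.** A CpG belongs to a region if its 0-based position
lies in the half-open interval `[start, end)`. The region level is
count-weighted,

    beta(s, r) = sum(m over CpGs in r) / sum(n over CpGs in r),

not the mean of per-CpG fractions. Count weighting matches the
read-pooling semantics of very-low-input libraries, where a CpG observed
by one read should not count as much as a CpG observed by six; it also
makes the meta-epigenome identity below exact. Regions with fewer than
`min_total_reads = 3` reads are marked missing — one or two reads give an
essentially binary, uninformative estimate.

**Meta-epigenomes.** All replicates of a cell type (the 8 + 2 + 1 pools
per donor, across donors) are combined by pooling their raw counts, which
is algebraically identical to aggregating the concatenation of their call
files (a tested invariant). The across-replicate standard deviation of
per-replicate `beta` is reported as the variability estimate; this SD is
this package's choice of spread statistic, since "initial assessment of
variability" is not otherwise formalized in the underlying design.

**Matrix assembly.** Regions missing in more than `max_missing = 20%` of
samples are dropped; remaining missing entries are imputed with the
per-region mean across samples. Mean imputation is neutral for the
standardized, regularized linear models downstream (an imputed entry sits
exactly at the feature mean, contributing zero signal); the imputation
mask is kept and every statistic that should ignore imputed values (the
mean-adjusted profiles) does so.

## 2. Region and region-set statistics

**Differential regions.** Per region, a Welch two-sample *t* test on
per-sample `beta` between two groups, Benjamini-Hochberg adjustment over
all tested regions, and a dual pass criterion: `q <= 0.05` **and**
`|mean difference| >= 0.167` in methylation-fraction units. The upstream
convention prints "0.167 percentage points", which is anomalously small
for a percentage-point threshold; this package reads it as a fraction
(16.7 p.p.). Both the FDR and the effect threshold are plain arguments,
so the literal 0.167-p.p. reading is one flag away. Degenerate regions
(zero variance in both groups) get p = 1 when the means agree and p = 0
otherwise rather than a failed test.

**Mean-adjusted region-set methylation.** For a sample `s` and region set
`S`, `Delta(s, S) = mean(beta(s, r), r in S, observed only) − g(s)`,
where `g(s)` is the sample's global CpG mean `sum(m)/sum(n)` over *all*
CpGs (not only those inside catalog regions; configurable). Subtracting
`g(s)` removes per-sample baseline shifts caused by cell number, coverage
and conversion chemistry, making 10-, 50- and 1,000-cell samples
comparable. The set mean is unweighted over regions because region sets
mix coverage regimes and the statistic compares samples, not regions.
Samples with fewer than 5 observed regions in the set are flagged
low-confidence. Set-level group comparisons use the two-sided Wilcoxon
rank-sum test (independent groups — not signed-rank), exact when both
groups have at most 25 samples and no ties, normal approximation with
continuity correction otherwise, with the dual threshold `p <= 0.05` and
`|Delta difference| >= 0.10` (10 p.p.).

**PCA and clustering.** Column-centered PCA via SVD (`prcomp`), with
variance-explained fractions and projection of held-out samples onto
fitted components; agglomerative clustering with Euclidean distance and
complete linkage for heat-map leaf ordering.

## 3. Enrichment

A query region list is tested against each set of a region-set database
relative to a universe (by default the analysis catalog — the regions
actually tested, mirroring the LOLA universe concept). A universe region
is "in" a set if it overlaps any set interval by at least one base
(half-open semantics), counted once regardless of multiplicity. The 2x2
table (a = query-in-set, b = query-out, c = background-in-set,
d = remainder) feeds Fisher's exact test. The default is **two-sided**
(symmetric for depletion), a deliberate divergence from LOLA's one-sided
default; `alternative = "greater"` restores the LOLA behaviour. Odds
ratios are reported raw (`ad/bc`, possibly infinite) and with the
Haldane-Anscombe 0.5 correction in a separate column; raw counts are
always emitted.

## 4. Elastic-net cell-type classification

Multinomial logistic regression with penalty
`lambda * [(1 − alpha)/2 * ||W||_2^2 + alpha * ||W||_1]`, fitted with
glmnet on the (imputed, complete) region matrix. Choices the upstream
description leaves open, declared here:

- `alpha = 0.5` by default, exposed as an argument.
- `lambda` selected by internal cross-validation as the **largest lambda
  within one standard error** of the minimum multinomial deviance.
- Features standardized to unit variance inside the fit; coefficients
  reported on the original scale.
- Multiclass handled natively as multinomial; one-vs-rest is used only
  for per-class ROC AUC reporting (midrank tie handling).
- Fold assignment hashes sample ids together with the run seed, so folds
  are reproducible and independent of row order; when donor annotation
  is supplied, all samples of one donor within a class stay in the same
  evaluation fold.

Signature regions are those with importance
`I(r) = sum_c |W(c, r)| > 0` at the selected lambda, with the per-class
coefficient sign pattern. Because planted discriminative regions within
one lineage edge are mutually redundant (they separate the same class
pair), the L1 component keeps a subset of each redundant group; the
signature is therefore a *sufficient* discriminative set, not an
exhaustive list of differential regions — recovery tests score it against
planted regions that carried their full effect and entered the feature
matrix.

## 5. Lineage reconstruction

For every cell type `c`, a classifier is trained on all other classes
(same alpha and lambda rule) and applied to the withheld samples of `c`;
row `c` of the cross-prediction matrix is their mean class-probability
vector. Edges are symmetrized by the arithmetic mean
`w(c, d) = (P(d|c) + P(c|d)) / 2` — the direction handling is not pinned
down upstream, so both the directed matrix and the symmetrized weights
are kept. Edges below `prune = 0.05` are removed (sub-noise probability
floor given 5+ remaining classes). The maximum-weight spanning tree
(greedy Kruskal, ties broken by the lexicographic node pair) summarizes
the graph as a testable topology; the tree summary is an addition of this
package so that lineage recovery can be asserted, the graph itself being
the primary output.

## 6. The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

- **Lineage-structured propensities.** Root region propensities are drawn
  from Beta(2, 2) — intermediate methylation with broad spread, the regime
  where regulatory regions are informative and planted shifts of 0.3
  rarely clip at the [0, 1] boundary. Each child inherits its parent's
  propensities; per edge, `n_shift = 50` randomly chosen regions shift by
  `0.3` with random sign, clipped to [0, 1]. Non-shifted regions are
  bit-identical between parent and child.
- **Design.** 7 cell types (HSC, MPP, CMP, MEP, GMP, MLP0, CLP in the
  default tree), 3 donors, and per donor eight 10-cell pools, two 50-cell
  pools and one 1,000-cell pool (11 pooled libraries), plus optional
  sparse single cells.
- **Read sampling.** Per cell and CpG the true state is
  Bernoulli(region propensity); read totals per CpG are Poisson with a
  pool-size-dependent mean (defaults 0.8 / 1 / 1.5 reads per CpG for
  10- / 50- / 1,000-cell pools — sub-1x coverage typical of small-pool
  libraries, rising slightly with input DNA complexity). Each read
  samples a random cell of the pool, so two reads on one CpG can hit the
  same cell and share its state. Observed states flip with conversion
  error rates `eps01 = 0.005` (unmethylated read seen methylated) and
  `eps10 = 0.02` (methylated seen unmethylated).
- **Single cells.** A CpG drops out entirely with probability
  `sc_dropout = 0.9`; covered CpGs draw a zero-truncated Poisson read
  count, so the covered fraction is exactly `1 − dropout`. (Plain Poisson
  after dropout would deflate the covered fraction by a further
  `exp(−lambda)`, breaking the covered-fraction contract.)
- **Determinism.** Every sample's stream is seeded by a hash of the
  master seed and the sample id, so adding a sample never perturbs the
  others and identical seeds reproduce the output tree byte for byte.

What it deliberately does **not** emulate: read-level sequence or
alignment artifacts, within-region CpG heterogeneity (per-CpG propensity
equals the region propensity, keeping the aggregation oracle exact; a
jitter option exists but defaults off), chromosome-scale genomes, donor
effects beyond sampling noise, and CNV/SNP confounders. A green recovery
test therefore establishes that the pipeline's statistics behave
correctly under the assumed sampling model — not that they are robust to
alignment bias or inter-individual regulatory variation.

## 7. Calibration and power at desk scale

Two consequences of the shallow-coverage design are worth spelling out
because they set what the tests can honestly assert:

- For a 10-cell pool, the per-region estimate carries *cell-sampling*
  noise of sd `sqrt(p(1−p)/10)` (about 0.16 at p = 0.5) on top of read
  noise. At 11 vs 11 samples this caps per-region Welch power below the
  0.9 recall target for a 0.3 shift, regardless of sequencing depth; the
  recall/false-discovery calibration test therefore uses 50-cell pools at
  2 reads/CpG, where the planted effect is resolvable. The null-FDR test
  (200 replicates) runs at default-like shallow coverage, where BH
  control holds regardless of power.
- The elastic net's signature is scored against planted regions that kept
  their full 0.3 magnitude after clipping and survived coverage filtering
  into the matrix; clipped shifts are real but smaller effects, and
  regions dropped for coverage are outside the classifier's feature
  space.

## 8. Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; the Bismark parser is the
  single conversion point (1-based inclusive to 0-based), covered by
  boundary tests at region start, end−1 and end.
- Zero-coverage CpG records are dropped at parse time with a logged
  count; `m > n` is impossible in the coverage dialect (methylated and
  unmethylated counts are separate columns) but is still rejected on
  write.
- Matrix TSVs print doubles with 17 significant digits, so write/read
  round-trips are exact.
- Argmax class prediction breaks probability ties toward the
  lexicographically first class; AUC uses midranks; Kruskal ties break on
  the lexicographic node pair — all paths are deterministic.
- `fisher.test` odds-ratio conditioning is avoided by computing the
  reported odds ratio directly from the table (`ad/bc`), with the
  Haldane-Anscombe correction only in the clearly-labelled corrected
  column.

## 9. Known limitations

- The generator's per-CpG homogeneity within regions understates
  within-region variance of real regulatory elements.
- Mean imputation shrinks group differences at imputed entries; at the
  default ~5% imputation rate this is negligible (tested at 0.05 MAE
  against the fully observed matrix), but matrices with heavy missingness
  should be filtered more aggressively instead.
- Cross-prediction probabilities from strongly separated classes saturate
  near 0/1, so lineage edge weights compress at large effect sizes; the
  spanning tree remains stable but the weights should not be read as
  distances.
- The Wilcoxon exact path requires tie-free data; ties silently fall back
  to the corrected normal approximation (the `wilcox.test` behaviour).
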