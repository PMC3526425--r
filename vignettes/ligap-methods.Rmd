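---
title: "Methods: Gaussian-process model selection over condition partitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian-process model selection over condition partitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligap)
```

## The problem

An experiment measures gene expression (log2 scale) over time under two or
more conditions — for example naive CD4+ T cells activated alone (Th0) or
polarized toward the Th1 or Th2 lineage — with replicates, possibly unequal
replicate counts per time point, and possibly missing values. For every gene
we want to know *which conditions behave alike and which differ* over the
whole time course, not merely whether some time point differs. Pointwise
tests ignore temporal correlation; classical whole-course F-tests do not
extend naturally beyond two groups and cannot express statements such as
"all conditions differ from each other".

## Hypotheses are partitions of the condition set

Every way of grouping the conditions into disjoint blocks is one hypothesis:
conditions in the same block share one latent temporal profile, distinct
blocks have independent profiles. For `N` conditions the hypothesis space is
all set partitions of the labels, of size the Bell number `B_N` (`B_2` = 2,
`B_3` = 5, `B_4` = 15). `enumeratePartitions()` orders them canonically —
fewest blocks first, then lexicographically by growth string — so for
(Th0, Th1, Th2) the sequence is: all together; Th2 alone; Th1 alone;
Th0 alone; all singletons. Runs are practical up to about 5 conditions
(52 hypotheses per gene); the enumeration is capped at 8.

## Per-block model: GP regression with a neural-network covariance

Each block's observations `y` (pooled over its conditions, replicates as
repeated inputs) are modeled as a zero-mean Gaussian process over time plus
iid Gaussian noise. The covariance is the non-stationary neural-network
kernel on bias-augmented inputs `x = (1, t/tmax)`:

    k(x, x') = sigma * asin( x' L x' / sqrt((1 + x' L x)(1 + x'' L x'')) ),
    L = diag(1/l^2)

The arcsine argument is strictly inside (−1, 1) for any finite inputs
(Cauchy–Schwarz with the +1 terms), so the kernel is always defined. Unlike
a stationary kernel, it allows fast dynamics early in the time course and a
flattening later — the typical shape after cell activation. Times are
scaled by the dataset maximum so hyperparameter magnitudes do not depend on
whether time is recorded in hours or days; the bias entry is the constant 1.

With Gaussian noise the marginal likelihood is analytic:
`log N(y | 0, K + noise*I)`. A hypothesis's evidence is the product of its
blocks' marginal likelihoods, and with equal hypothesis priors Bayes'
theorem turns the evidences into posterior probabilities (computed with
max-shifted exponentiation). The per-condition *differential-regulation
score* is the summed posterior of the partitions in which that condition is
a singleton block — for three conditions, the score of Th2 is
`P(H2 | D) + P(H5 | D)` in the canonical numbering — and the *all-different
score* is the posterior of the all-singletons partition.

## Hyperparameters: one shared set per hypothesis

The kernel hyperparameters (two lengthscales, the signal variance) and the
noise variance are estimated by type-II maximum likelihood: BFGS on the log
scale with analytic gradients, convergence tolerance 1e-6, at most 200
iterations, restarted from 10 initial values by default (one fixed midpoint
start plus log-uniform draws: lengthscales in [0.05, 5] scaled-time units,
signal variance in [0.1, 10] and noise variance in [0.01, 1] times the data
variance). The noise variance is bounded below at 1e-6 times the data
variance.

Two choices matter for the validity of the evidence comparison and deserve
their rationale here:

* **One centering constant per gene.** A zero-mean GP needs the dominant
  offset removed. If each block were centered by its own mean, hypotheses
  with more blocks would receive extra free location parameters and —
  crucially — the hypotheses would no longer model *the same data vector*,
  making their marginal likelihoods incomparable. All blocks of a gene are
  therefore centered by the gene-wide mean.
* **One hyperparameter set per hypothesis.** Within a hypothesis the blocks
  are independent GPs given the hyperparameters (block-diagonal
  covariance), but they share one jointly optimized hyperparameter set.
  If every block optimized its own set, a finer partition would gain
  roughly half a nat of spurious evidence per extra free hyperparameter
  (the usual optimism of maximized likelihoods), systematically biasing the
  posterior toward over-splitting: on synthetic equal-profile genes the
  single-block truth was recovered for only ~73% of genes with free
  per-block hyperparameters, versus ~90% with a shared set, while recovery
  of genuinely distinct blocks was unaffected. Sharing also reflects the
  biology: smoothness and measurement noise are properties of the gene and
  platform, not of a hypothetical grouping.

Genes with fewer than two non-missing observations in some condition cannot
support all block fits; they are flagged unanalyzable, reported, and
excluded from calls.

## Calling rule

A condition is called differentially regulated when its score exceeds
`probCutoff` (default 0.9, the conventional strong-evidence grade) *and*,
when `requireFoldChange` is on (default), its fitted profile differs from
the fitted profiles of **all** other conditions by at least
`foldChangeLog2` (default 1.0 = two-fold) at some shared time point on the
grid of observed times (`>=` at the boundary). Fold changes are evaluated
on GP posterior means rather than raw replicates, which makes the filter
robust to single-replicate outliers; the per-condition means come from the
all-singletons hypothesis fit. "All different" is called when the
all-singletons posterior exceeds the cutoff. Scores are posterior
probabilities, not p-values; no multiple-testing correction is applied.

## Uncertainty display and downstream summaries

`plotProfiles()` draws, per condition, the posterior mean on a dense grid
with a 95% band of ±1.96 posterior standard deviations of the *latent
function* (observation noise excluded — the band describes the estimated
profile, not where new replicates would fall; an interpretation, since
either convention is defensible). Every figure writes its numbers to a
companion TSV. `pcaScores()` projects the per-gene score vectors (one score
per condition plus the all-different score) onto their first two principal
components — centered, unscaled (all features already live on [0, 1]), with
loadings sign-fixed so each loading's largest-magnitude entry is positive,
making coordinates bit-reproducible. `clusterHeatmap()` clusters
genes by complete-linkage hierarchical clustering of Euclidean distances
between concatenated per-condition fitted profiles, standardized per gene
to mean 0 / sd 1 across all time points and conditions; the number of
clusters `k` is a user choice, and the heat map's diverging color scale is
symmetric around 0.

## TF-binding enrichment

Binding predictions arrive as a table of (TF, gene, binding p-value) over a
scored promoter universe; this package does not compute them. Targets of a
TF are genes with binding p-value strictly below the cutoff (default 0.01).
Over-representation of targets in a query gene set (for example the genes
called up-regulated in one condition) is tested one-sidedly: the p-value is
the hypergeometric upper tail of the 2×2 table over the background, which
equals the one-sided Fisher exact test. The background is the scored
universe, not the whole array, because binding calls exist only for scored
promoters. Motifs can be pooled into families through an alias map (useful
when several motifs of one family share binding specificity);
Benjamini–Hochberg-adjusted p-values are reported alongside raw ones. The
overlap between predicted and experimentally observed target sets is
summarized by the same hypergeometric tail — a stand-in for an unspecified
correlation statistic, and documented as such.

## The synthetic-data generator

`simulateDataset()` emulates the structure of an early-differentiation
experiment: three conditions, times 0, 12, 24, 48 h in three replicates and
72 h in two (14 samples per condition), defaults chosen to match that
design shape. Per gene a true partition is drawn from `truth_mix`; each
block receives one latent trajectory — by default a logistic rise or fall
(baseline in a realistic log2-intensity range, amplitude 0.5–2.5, midpoint
6–36 h), which is fast-early/slow-late without reusing the analysis kernel
as the generator (a `gp-draw` family exists for matched-model checks, and
`exp-saturating` for a second non-stationary shape). Distinct blocks sit on
a baseline ladder whose gaps scale with `effect_size` and are redrawn until
every pair of block trajectories differs by at least `effect_size` log2
units at some grid time, so ground truth is unambiguous under noise.
Observations add iid Gaussian noise (default sd 0.3 log2 units, a typical
between-replicate scatter for normalized arrays); `missing_rate` masks
entries at random. Everything derives deterministically from the seed.

What the generator does **not** emulate: probe-level effects, batch
structure, intensity-dependent variance, correlated replicates, or
non-Gaussian outliers. Passing recovery tests therefore demonstrates that
the engine identifies trajectory-sharing structure under the stated noise
model, not that the error model of any particular platform is correct.

At the default study conditions (effect 2.0, noise sd 0.3, 100 genes per
true partition, 3 restarts) the modal-posterior partition matches the truth
for ≥ 85% of genes in every class, and on equal-profile genes the
all-different score exceeds 0.9 in under 5% of cases. These sizes — 100
genes per class, restart counts of 3 in the automated checks versus 10 as
the analysis default — are the package's chosen benchmark scale; larger
runs sharpen the estimates but do not change the qualitative picture.

## Numerical choices and degenerate inputs

* Cholesky factorizations add an escalating jitter on failure: starting at
  1e-6 times the mean diagonal, doubled up to 6 times, then an error names
  the offending block.
* Posterior predictive variances are clamped at 1e-12 to stay positive.
* Constant-valued blocks short-circuit to the zero-signal model with the
  noise pinned at its floor; the posterior mean is the constant.
* Sub-seeds are derived counter-style from (run seed, gene index, sorted
  block bitmasks, restart index), so results are independent of gene
  processing order; identical seeds give byte-identical result files.
* Ties in `which.max` over posteriors resolve to the coarser partition
  (earlier canonical index), which only matters for exactly equal
  evidences.

## Known limitations

* Cost grows as `B_N` per gene; beyond 5 conditions runs are slow and
  beyond 8 unsupported.
* Replicates are treated as iid repeated observations of one latent
  trajectory; there is no replicate- or donor-specific random effect, and
  no paired-sample mode.
* Type-II ML uses point estimates of hyperparameters; the evidence does not
  integrate over them. The shared-hyperparameter design above removes the
  dominant bias this causes, but weak residual optimism toward finer
  partitions remains at very small sample sizes.
* The fold-change filter compares fitted means at observed time points; a
  separation that exists only between observed times is not credited.
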