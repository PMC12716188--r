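---
title: "Models and methods behind the chicken Treg signature workflow"
author: "tregsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the chicken Treg signature workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tregsig)
```

## The problem

Mammalian regulatory T cells (Tregs) are defined by the transcription
factor FoxP3 and the IL-2 receptor alpha chain CD25. The chicken
counterpart is poorly characterized: CD25 sorting alone does not isolate a
clean FOXP3-positive population, so the identification has to proceed
through transcriptomics. The workflow in this package mirrors the
computational side of that identification:

1. **Single cell**: quality-filter a CD4+ single-cell count matrix,
   cluster it at high resolution, find the clusters with elevated *FOXP3*,
   and score candidate marker genes for those clusters with a bespoke
   mean-expression-ratio statistic.
2. **Bulk**: negative-binomial differential expression across FACS-sorted
   CD25^high^ / CD25^low^ / CD25^negative^ CD4+ populations with a sex
   covariate, written from scratch (normalization, dispersion estimation,
   Wald and likelihood-ratio tests).
3. **qPCR**: ΔΔCT relative quantification of *FOXP3* against a reference
   gene with one-way ANOVA and Tukey HSD group comparisons.

Every stage runs on synthetic data whose generating process is part of the
package, with ground truth recorded, so each statistical claim is backed
by a recovery test.

## Count model

One negative-binomial parameterization is used everywhere: mean $\mu$,
dispersion $\alpha > 0$, variance $\mu + \alpha\mu^2$ (`size = 1/alpha` in
R's `rnbinom`). The simulators and the differential-expression engine
share it, so dispersion-recovery tests are self-consistent.

## The synthetic-data generator

`simulate_sc_dataset()` emulates the *structure* the single-cell analysis
assumes, at desk scale (default 5,000 cells x 2,000 genes versus roughly
20,000 cells in the real dataset):

* 22 clusters; the first two are the Treg clusters at 4.1% and 3.0% of
  cells, the reported sizes of the two FOXP3-positive clusters. The
  remaining fractions are free parameters in the source material; they are
  set on a mild ramp (about 3-6.5% each), which keeps every cluster above
  the resolution limit of modularity-based community detection at the
  working resolution of 1.5.
* Cluster identity is carried by planted expression programs. Each
  non-Treg cluster over-expresses 60 genes at folds drawn from U(4, 9) -
  distinct immune cell states differ by hundreds of genes, and this is
  what makes them separable in a 50-component PCA. Each Treg cluster
  carries (i) its 10-gene marker panel at fold 8 (the genes the ratio
  score is meant to recover, named after canonical Treg markers such as
  *CTLA4*, *TNFRSF18*, *IL2RA*, *SIVA1*, *ITGB8*), (ii) a broad unique
  program of 80 genes at folds U(3, 5), and (iii) a 40-gene program shared
  between both Treg clusters at fold 5. Panel, unique-program and shared
  genes all sit at a common moderate baseline: on the log-scale ratio
  score, equal baselines make fold ordering imply score ordering, so the
  designated panel is the top-ranked marker set by construction - which is
  exactly the premise of the marker statistic. The shared program scores
  near 1 for either Treg cluster (the other Treg cluster is the runner-up)
  and therefore never pollutes the per-cluster marker list, while still
  separating Tregs from everything else.
* *FOXP3* has a low baseline (0.02 counts/cell, so under 10% of cells
  express it in any non-Treg cluster, as the narrative requires) and is
  elevated 40-fold in the first and 20-fold in the second Treg cluster.
  With dispersion 1, the expected expressing fraction in the first Treg
  cluster is about 45%, close to the reported value.
* Per-cell library sizes are log-normal (sigma 0.3) so scaling
  normalization is non-trivially exercised; two batches differ by per-gene
  log-scale offsets (sigma 0.15), the location-shift structure that
  per-batch centering of principal components removes exactly.
* Mitochondrial / ribosomal genes (8% of genes, `MT-` / `RPL` prefixes -
  the flagging convention, since the source does not state one) have
  elevated baselines (3x / 1.5x). This puts the average cell's flagged
  count fraction near 14%: the 20% QC filter then removes only the upper
  tail (about 1% of cells), matching a study in which nearly all targeted
  cells survived QC. The joint (mitochondrial + ribosomal) fraction is
  filtered, following the wording "mitochondrial/ribosomal"; whether the
  cutoffs were meant jointly or separately is not stated.

What the generator deliberately does **not** emulate: ambient RNA,
doublets, UMI chemistry, gene-gene correlation within programs, and the
heavy-tailed cluster-size distribution of real tissues. Passing recovery
tests therefore demonstrate that the pipeline's statistics do what they
claim on data satisfying their assumptions - not that real chicken spleen
data would be recovered this cleanly.

`simulate_bulk_dataset()` plants log2 effects for the CD25 levels
(reference: negative) and a sex effect on a gene-wise baseline drawn
uniformly from 20-2,000 counts, with log-normal library sizes. The
default acceptance configuration plants balanced directions (100 genes up,
100 down at |log2 FC| = 2 among 2,000): one-directional planting would
bias the median-of-ratios size factors of the affected group and hence
every recovered fold change, whereas real contrasts - including the
reported one - contain both directions.

`simulate_qpcr_dataset()` draws the reference CT around a fixed value and
adds the group's true ΔCT plus Gaussian noise to form the target CT, so
zero noise recovers the truth exactly.

## Single-cell stage choices

* **QC boundaries** are inclusive on the keep side (a cell with exactly
  200 detected genes, exactly 15,000 counts, or exactly 20% flagged counts
  is kept), matching the >=/<= reading of the upstream tool's parameter
  names. An all-zero cell has flagged fraction 0 by definition (it fails
  `min_genes` anyway). Cells are filtered before genes, in one pass each.
* **Normalization**: every cell is scaled to the median total count (the
  common upstream default; configurable) and transformed by log(1 + x).
* **HVG statistic**: variance/mean of the normalized log values,
  standardized within 20 equal-frequency mean bins, ties broken by gene
  index; 1,000 genes are kept by default (half the default gene space).
  A cancellation guard treats variances below 1e-10 x (mean + 1)^2 as
  exactly zero so constant genes always rank last.
* **PCA**: per-gene centering only (no unit-variance scaling), 50
  components by default, eigendecomposition of the gene covariance, sign
  fixed by making the largest-magnitude loading positive. Rank-deficient
  input returns the available components with a warning.
* **Batch correction**: per-batch mean-centering of each principal
  component (global mean restored). The original analysis used an
  iterative clustering-based tool; centering is a deliberate
  simplification that exactly removes the location-shift batch effects the
  generator produces, and is documented as such.
* **kNN graph**: k = 15 (upstream default), Euclidean distances, ties
  broken by cell index, union symmetrization. Edge weights use a locally
  adaptive Gaussian kernel `exp(-d^2 / (sigma_i sigma_j))` with `sigma_i`
  the distance to the k-th neighbor, giving weights in (0, 1].
* **Clustering**: Leiden optimization of resolution-parameterized
  modularity (via igraph), resolution 1.5, seeded, labels relabeled by
  decreasing size, 0-based (the numbering convention of the upstream
  ecosystem, which is why "cluster 9" and "cluster 15" are 0-based names
  in the source material).

## The marker score

For gene $g$ and designated Treg cluster $c$, order clusters by mean
normalized log expression of $g$. If $c$ is not the **strict, unique**
maximum the score is 0 (a tie at the top is read conservatively as "not
the top cluster"). Otherwise

$$s(g, c) = \frac{\bar{x}_{c,g}}{\bar{x}_{(2),g}}$$

with $\bar{x}_{(2),g}$ the second-highest cluster mean. If that second
mean is zero, the score is the cluster mean divided by the smallest
positive mean in the table and flagged "infinite-like", which preserves
the ranking without special-casing downstream sorts. The log layer is used
for the means (the source does not state the layer; the choice is
documented and kept consistent everywhere). Percent-expressing is always
computed on the raw count layer (count > 0).

Candidate markers additionally need a significant one-vs-rest Wilcoxon
rank-sum test: Benjamini-Hochberg adjusted across genes within the
cluster, cutoff 0.05 by default (the source reports "significantly higher"
without naming a correction). The log2 fold change attached to each
marker is `log2((expm1(mean log in cluster) + 1e-9) / (expm1(mean log in
rest) + 1e-9))`, the convention of upstream rank-genes statistics.

FOXP3-positive clusters are called by two rules: (a) positive-direction
one-vs-rest Wilcoxon on *FOXP3*, BH-adjusted across clusters, p <= 0.05;
and (b) at least 10% of the cluster's cells expressing *FOXP3* - the 10%
figure comes from the narrative that non-Treg clusters stay below it.
Rule (b) is what keeps a cluster whose high mean is driven by a single
extreme cell from being called.

### Wilcoxon implementation

Both group sizes <= 8: exact permutation enumeration over all
$\binom{n}{n_1}$ assignments of the (mid)ranks - ties handled naturally.
Larger groups: normal approximation with tie-corrected variance
$\sigma^2 = \frac{n_1 n_2}{12}\left((n+1) - \frac{\sum_t (t^3 - t)}{n(n-1)}\right)$
and a 0.5 continuity correction. All values tied across both groups gives
p = 1. The acceptance suite checks the approximation against a
100,000-resample Monte-Carlo permutation oracle; agreement is required to
2% relative error plus three times the oracle's own binomial standard
error (at p around 0.01 the oracle's noise alone is about 3% relative, so
a bare 2% bound would test the oracle rather than the approximation).

## Bulk differential-expression engine

* **Size factors**: median across reference genes (nonzero in every
  sample) of the count over the gene's geometric mean; the median is taken
  on the linear ratio scale, exactly as the formula reads. If no reference
  gene exists the error suggests a pseudo-reference fallback rather than
  applying one silently.
* **Dispersion**: gene-wise method of moments on normalized counts with
  OLS design-based means - from $E(q_j - \mu_j)^2 = \mu_j / s_j + \alpha
  \mu_j^2$ - floored at 1e-8, then moderated by empirical-Bayes shrinkage
  on the log scale toward a central value. The prior variance is the
  excess of the robust spread of the log gene-wise estimates over their
  theoretical sampling noise, `trigamma((n - p) / 2)`. The moderation is a
  deliberate design choice: with n = 12 and p = 4 the raw per-gene
  estimator has roughly 50% coefficient of variation, and plugging it into
  a normal-reference Wald test inflates the type-I error to ~0.10 and the
  pipeline's false discovery rate to ~0.2, far outside this package's own
  calibration requirements. Shrinkage with a data-estimated prior width
  collapses to the central value when gene-wise spread is pure noise and
  preserves genuine dispersion heterogeneity - the same reasoning as the
  established empirical-Bayes engines in this field. The unmoderated
  estimates remain available (`moderate = FALSE`) and are what the
  method-of-moments recovery tests exercise.
* **GLM fit**: log link, offset `log(s_j)`, IRLS at fixed dispersion,
  convergence when the largest coefficient update is below 1e-8 (cap 100
  iterations, non-convergence flagged; linear predictors clamped to
  +-30 to keep exponentials finite). All-zero genes are skipped and
  flagged. Treatment coding: `cd25_group` reference "negative", sex
  reference alphabetical; contrasts high-vs-negative, low-vs-negative and
  high-vs-low are contrast vectors on the coefficients.
* **Wald test**: standard error from the inverse observed information
  $\sum_j x_j x_j^\top \mu_j (1 + \alpha y_j) / (1 + \alpha \mu_j)^2$,
  p two-sided normal. **LRT**: full (`~ sex + CD25`) versus reduced
  (`~ sex`) at the same gene-wise dispersion; the statistic is clamped at
  zero against convergence round-off; degrees of freedom are the design
  rank difference (2 here), computed generically; identical designs return
  p = 1. **Multiple testing**: BH within each contrast, NAs excluded from
  the test count. No LFC shrinkage and no independent filtering of
  low-count genes; the base mean is reported so users can filter.
* The Venn partition of significant genes uses the Wald adjusted p-values
  (the source does not state whether Wald or LRT membership defined its
  diagram; the cutoff is exposed as configuration). Z-scores for the
  heatmap standardize each gene's normalized group means to zero mean and
  unit sample SD, constant genes mapping to zeros.

## qPCR stage

ΔCT = target CT - reference CT per sample; ΔΔCT subtracts the
**arithmetic mean** ΔCT of the control group (equivalently, the geometric
mean on the linear scale), so the control aggregate's fold change is
exactly 1; fold = 2^-ΔΔCT. Group summaries are mean +- SD of per-sample
folds, matching the figure convention. ANOVA and Tukey HSD run on the
fold scale by default (the figures annotate fold plots); a `log` scale
flag is exposed because the analysis scale is not stated. The degenerate
all-constant case returns F = 0, p = 1. Stars: * <= 0.05, ** <= 0.01,
*** <= 0.001.

## Problem sizes used by the test suite

The recovery tests run 20 seeds of the default preset (5,000 cells x
2,000 genes); NB calibration uses 2,000 genes at n = 4 per group with a
sex covariate and dispersion 0.1; the Wilcoxon oracle uses 50 cases of
100-200 observations at 100,000 resamples; unit tests use fixtures from 7
cells up to a few thousand. These sizes are the package's own choices:
large enough that every asserted band is meaningful, small enough that
the full suite runs on a laptop in minutes.

## Known limitations

* The batch model (location shifts) and its correction (centering) are
  intentionally simpler than iterative integration methods; data with
  nonlinear batch distortions would need the latter.
* Wald p-values use the normal reference; with moderated dispersions this
  is calibrated at the simulated conditions, but at very small sample
  sizes a t-type reference would be more conservative.
* The ratio score depends on the expression layer and on the strict-top
  tie rule; both are documented choices where the source is silent.
* Real-data headline figures (23 clusters, 5,018 DEGs, specific marker
  counts) depend on the deposited reads and external preprocessing and
  are outside what the synthetic workflow can or should reproduce.
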