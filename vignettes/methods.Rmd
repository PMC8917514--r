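---
title: "Neighborhood-distribution feature selection: model and design"
author: "knnfs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood-distribution feature selection: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knnfs)
```

## The statistic

Let $x_{cg}$ be the raw UMI count of gene $g$ in cell $c$, and let
$N(c)$ be the $k$ cells nearest to $c$ in a 30-component PCA of the
log-normalized matrix ($k = \lfloor\sqrt{n}\rfloor$ by default, exact
Euclidean search). For every cell with $x_{cg} > 0$ we form the
neighborhood sum

$$ s_{cg} = x_{cg} + \sum_{c' \in N(c)} x_{c'g}, $$

and compare the empirical distribution of $s_{cg}$ over expressing
cells with its *random-neighbor null*: the distribution of the same sum
when the $k$ cells are drawn at random from the dataset. Writing $P$
for the empirical count distribution of the gene over all cells and
$P^{+}$ for its restriction to expressing cells, the null is the exact
convolution $P^{+} * P^{*k}$ — one draw from an expressing center cell
plus $k$ independent draws from all cells, mirroring the conditioning
of the observed statistic. The two distributions are compared with the
1-Wasserstein distance, which for distributions on the line is the
integral of the absolute CDF difference. A gene expressed by
transcriptomically similar cells has neighborhood sums far above the
null and hence a large distance; a gene expressed at random matches its
null almost exactly.

Both conditioning choices are exposed: `conditionNull = FALSE` uses the
plain $P^{*k}$ (no center-cell term), and `includeSelf = FALSE` drops
the center's own count from the sums. The defaults (both `TRUE`) keep
the observed and null laws structurally identical, so that a gene with
a point-mass count distribution has distance exactly zero.

Raw distances grow with expression level, so genes are binned into
`nWindows = 100` equal-count windows of log mean expression and the
window median is subtracted (`correction = "mean"` is available for
comparison; the median is robust to the handful of strongly localized
genes inside a window). After correction the median corrected distance
of every window is zero by construction.

### Selection rule

Corrected distances are ranked in decreasing order (ties broken by
gene identifier so runs are reproducible). With a numeric `nFeatures`
the top of the ranking is taken directly. In automatic mode the cut-off
is the *knee* of the ranked curve: the point with maximum perpendicular
distance below the chord joining the first and last point of the curve.
Points are selected strictly before the knee, and the selection is then
intersected with `correctedDistance >= minDist` (default 0.1), which
removes near-flat tails when the curve has no pronounced elbow. When
every corrected distance is equal the knee is undefined; the
implementation warns and falls back to the threshold alone. The signed
(below-chord) variant of the knee was chosen over the absolute distance
because the first point past the elbow of a convex decreasing curve
lies below the chord; taking the maximum absolute distance can land on
a tail point and overshoot the elbow.

## Null computation

The $k$-fold convolution is computed on the dense integer grid
$0..k\,x_{\max}$. Below a grid length of 2048 an exact
square-and-multiply accumulation is used; above it, a single FFT power
step (round-off at the $10^{-12}$ level; negative round-off mass is
clipped and the result renormalized). A seeded Monte-Carlo estimator
(`nullMode = "montecarlo"`) draws one expressing cell plus $k$ cells
with replacement; tests require the two estimators to agree within
total-variation 0.01 at $10^5$ draws. Genes expressed in fewer than
`minCellsPerGene = 5` cells are not scored: their distance is 0, they
join no window and are never selected.

## The simulator

`simulateCounts()` emulates a splat-style gamma-Poisson generator, the
standard model for UMI counts:

* baseline gene means $\mu_g \sim \mathrm{Gamma}(0.6, \text{rate}=0.3)$;
* with probability `deProb`, a (population, gene) pair receives a
  lognormal DE factor ($\mathrm{lognormal}(0.1, 0.4)$, inverted with
  probability 0.5 for down-regulation);
* library sizes $L_c \sim \mathrm{lognormal}(11, 0.2)$ (about 60,000
  counts per cell);
* Poisson rates $L_c\, \mu_g f_{pg} / \sum_g \mu_g$, jittered by a
  mean-one gamma multiplier with CV
  $(0.1 + 1/\sqrt{\lambda})\sqrt{60/\chi^2_{g,60}}$ — the
  biological-coefficient-of-variation layer that gives the
  negative-binomial marginal observed in real UMI data.

All hyperparameters follow the published splat defaults and are
exposed in `simParam()`. Two deliberate simplifications:

* **Common baseline normalizer.** Rates are normalized by
  $\sum_g \mu_g$ (the baseline), not per population. Non-DE genes
  therefore have *identical* expected expression in every population
  and the stored DE factors are exact expected-mean ratios, which makes
  ground-truth bookkeeping exact; the price is that expected library
  sums differ slightly between populations (fractions of a percent at
  low `deProb`).
* **Deterministic labels.** Cells are apportioned to populations by
  largest remainder, so population sizes are exact and clustering
  metrics have a fixed ground truth. The default design is 10,000
  cells, 15,000 genes, nine populations at abundances
  25/20/15/10/10/7/5.5/4/3.5%.

At these depths well over half of the count matrix is non-zero, so the
counts are stored dense (integer); peak memory for the default design
is about 2 GB.

The simulator does **not** model dropout beyond sampling zeros, batch
effects, expression outliers, doublets or trajectories. Passing
recovery tests on these data shows that the selector finds genuinely
localized genes under realistic NB noise and class imbalance — not that
it is robust to batch structure or ambient contamination.

## Evaluation protocol

`recoveryExperiment()` mirrors the standard benchmark loop: simulate,
select `nFeatures` genes per method, re-embed the cells on the selected
submatrix (30 PCs, $k=\lfloor\sqrt{n}\rfloor$), run Leiden community
detection (modularity objective) and score the communities against the
true labels with NMI and ARI. The Leiden resolution is matched to the
true number of populations by bisection (20 iterations, nearest count
as fallback), since cluster count is monotone in resolution only in
expectation. Baselines: per-gene standard deviation of log-normalized
expression (`std`), within-mean-bin z-scored variance/mean ratio
(`dispersion`, the classic highly-variable-genes recipe), and a seeded
`random` draw.

NMI is $2I(T;L)/(H(T)+H(L))$ computed from the contingency table (the
log base cancels); when both labelings are a single constant class it
is defined as 1. ARI uses the standard pair-counting form. The cosine
silhouette assigns $s(c)=0$ to cells in singleton clusters, where the
textbook formula is undefined. The Jaccard index of two empty gene
sets is defined as 0. In the ribosomal/mitochondrial report the
default denominator is the number of prefix-matching (`RPS`/`RPL`/
`MT-`, case-insensitive) genes in the dataset; a `"selected"`
denominator variant is provided because both conventions appear in the
literature.

## The annotation algorithm

`matchPopulations()` assigns marker-defined labels to precomputed
clusters: marker-gene expression is smoothed over the KNN graph (mean
over the $k$ neighbors, self excluded by default — a flag restores
self-inclusion), rank-normalized per gene to $(0,1]$ (average ranks for
ties), averaged over the label's markers, summarized per cluster by the
70th percentile (linear interpolation between order statistics), and
each cluster takes the best-scoring label. With
`allowIntermediate = TRUE`, labels within 0.05 of the maximum merge
into a composite label. All-zero score rows are reported as
`"unassigned"` rather than an arbitrary argmax.

## Problem sizes and numerical conventions

Tests and the acceptance script use scaled designs — typically 2,000
cells by 3,000 genes for recovery experiments and the full
10,000 x 15,000 design only where the dataset itself is under test —
five seeds per experiment, chosen to keep the full suite in the tens
of minutes on a single core while leaving the recovery effects well
clear of seed noise. Distance ties in the KNN search are broken toward
the lower cell index; PCA component signs are fixed by making each
component's largest-magnitude score positive; all randomness flows
from the single seed in the parameter objects.

## Known limitations

* The observed and null distributions ignore the overlap of
  neighborhoods of nearby cells; distances of strongly co-localized
  genes are therefore correlated, and the ranking should be read as a
  whole rather than gene-by-gene evidence.
* Exact KNN is $O(n^2)$ in cells — fine at desk scale (tens of
  thousands of cells), not for atlases.
* The knee rule assumes a convex decreasing ranked curve; on curves
  with several elbows it picks the most prominent one.
* `h5ad` input would require an HDF5 reader, which the package does
  not bundle; use MTX directories or CSV.
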