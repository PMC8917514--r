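# knnfs

Feature selection for single-cell RNA-seq count matrices based on the
local expression structure of the k-nearest-neighbor (KNN) graph of
cells, together with a splat-style count simulator with ground truth,
clustering-agreement metrics, and a marker-driven cluster annotation
algorithm.

## The problem and the method

Before clustering or embedding a single-cell dataset, analysts select a
few hundred "informative" genes. Classical selectors rank genes by
variance or dispersion, which confounds biological signal with the
strong mean-variance trend of UMI counts. `knnfs` instead asks a
spatial question on the KNN graph of cells: *is this gene expressed by
cells that are transcriptomically close to each other?*

For every gene:

1. Build the KNN graph: library-size normalize, `log1p`, PCA (30
   components), exact Euclidean KNN with `k = floor(sqrt(n_cells))`.
2. **Observed distribution.** For each cell with positive expression,
   sum the gene's counts over the cell's k neighbors (plus its own
   count). The empirical distribution of these sums over expressing
   cells concentrates at high values when expression is localized.
3. **Null distribution.** The law of the same sum when the k cells are
   drawn at random, computed exactly as the k-fold convolution of the
   gene's empirical count distribution `P` (convolved once more with
   the distribution over expressing cells, mirroring the conditioning
   of the observed statistic). A seeded Monte-Carlo estimator is
   available as a cross-check.
4. **Distance.** The 1-Wasserstein distance
   `W = ∫ |F_obs − F_null| dx` between the two distributions.
5. **Correction.** Genes are binned into `w = 100` equal-count windows
   of log mean expression and the window median is subtracted,
   removing the expression-level trend of `W`.
6. **Selection.** Corrected distances are ranked; the cut-off is either
   a requested number of genes or the knee of the ranked curve,
   intersected with a minimum corrected distance (0.1).

The package also provides: a gamma-Poisson (splat-style) simulator with
exact population abundances and stored ground truth (`simulateCounts`),
NMI/ARI/cosine-silhouette metrics and baseline selectors for
benchmarking (`recoveryExperiment`), and the percentile-based
population-matching algorithm for labeling clusters from marker lists
(`matchPopulations`).

## Worked example

```r
library(knnfs)

## 1,000 cells, 2,000 genes, 9 populations, 10% DE probability
sim <- simulateCounts(simParam(nCells = 1000, nGenes = 2000,
                               deProb = 0.1, seed = 7))
tbl <- selectFeatures(sim, fsParam(seed = 7), verbose = TRUE)
#> building neighbor graph (1000 cells, 2000 genes)
#> k = 31; scoring genes
#> 38 genes selected

head(as.data.frame(tbl[order(tbl$rank), ]), 5)
#>              geneId meanExpr rawDistance window correctedDistance rank selected
#> Gene00965 Gene00965   652.67        5592    100            4477.2    1     TRUE
#> Gene01999 Gene01999   233.31        2091    100             975.5    2     TRUE
#> Gene00212 Gene00212   184.32        1718     99             947.4    3     TRUE
#> Gene00046 Gene00046   232.28        1751    100             635.7    4     TRUE
#> Gene00976 Gene00976    94.14        1047     94             612.1    5     TRUE

## ground truth: 97% of the auto-selected genes are truly DE, against
## a 10% per-(population, gene) DE rate
mean(deFlags(sim, union = TRUE)[selectedGenes(tbl)])
#> [1] 0.9736842
```

`rawDistance` is the Wasserstein distance between the observed
neighborhood-sum distribution and its random-neighbor null;
`correctedDistance` is the same after subtracting the median of its
expression window; the knee of the ranked corrected distances sets the
automatic cut-off (here 38 genes).

A command-line front end with `run`, `simulate`, `evaluate` and
`annotate` subcommands is installed at
`system.file("scripts", "knnfs", package = "knnfs")`.

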