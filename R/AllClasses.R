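#' @import methods
#' @importFrom stats median quantile rbinom rgamma rlnorm rnorm rpois var
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' Parameters for neighborhood-distribution feature selection
#'
#' `FSParam` bundles every tunable of the feature-selection pipeline:
#' neighborhood size, PCA rank, window count for the expression-trend
#' correction, the selection rule and the null-distribution estimator.
#'
#' @slot k Neighborhood size. `NA` means automatic:
#'   `floor(sqrt(n_cells))`.
#' @slot nPCs Number of principal components for the embedding in which
#'   nearest neighbors are found (default 30).
#' @slot nWindows Number of equal-count windows of log mean expression
#'   used by the median correction (default 100).
#' @slot nFeatures Number of genes to select; `NA` means automatic
#'   knee-point detection on the ranked corrected distances.
#' @slot minDist Minimum corrected distance a gene must reach to be
#'   selected in automatic mode (default 0.1).
#' @slot seed Integer seed controlling every stochastic step.
#' @slot nullMode `"convolution"` (exact, default) or `"montecarlo"`.
#' @slot nMC Number of Monte-Carlo draws when `nullMode = "montecarlo"`.
#' @slot minCellsPerGene Genes expressed in fewer cells are not scored.
#' @slot includeSelf Whether the neighbor sum adds the center cell's own
#'   count (default `TRUE`).
#' @slot conditionNull Whether the null conditions on an expressing
#'   center cell, mirroring the observed distribution (default `TRUE`).
#' @slot correction `"median"` (default) or `"mean"` window statistic.
#' @slot logNormalize Whether to library-size normalize and log1p the
#'   counts before PCA (default `TRUE`).
#'
#' @seealso [fsParam()] for the user-facing constructor.
#' @export
setClass("FSParam",
    representation(
        k = "integer",
        nPCs = "integer",
        nWindows = "integer",
        nFeatures = "integer",
        minDist = "numeric",
        seed = "integer",
        nullMode = "character",
        nMC = "integer",
        minCellsPerGene = "integer",
        includeSelf = "logical",
        conditionNull = "logical",
        correction = "character",
        logNormalize = "logical"
    )
)

setValidity("FSParam", function(object) {
    msg <- NULL
    if (!is.na(object@k) && object@k < 1L)
        msg <- c(msg, "'k' must be a positive integer or NA (automatic)")
    if (object@nPCs < 1L)
        msg <- c(msg, "'nPCs' must be >= 1")
    if (object@nWindows < 1L)
        msg <- c(msg, "'nWindows' must be >= 1")
    if (!is.na(object@nFeatures) && object@nFeatures < 1L)
        msg <- c(msg, "'nFeatures' must be >= 1 or NA (automatic)")
    if (object@minDist < 0)
        msg <- c(msg, "'minDist' must be non-negative")
    if (!object@nullMode %in% c("convolution", "montecarlo"))
        msg <- c(msg, "'nullMode' must be 'convolution' or 'montecarlo'")
    if (object@nMC < 1L)
        msg <- c(msg, "'nMC' must be >= 1")
    if (!object@correction %in% c("median", "mean"))
        msg <- c(msg, "'correction' must be 'median' or 'mean'")
    if (is.null(msg)) TRUE else msg
})

#' Construct feature-selection parameters
#'
#' @param k Neighborhood size, or `"auto"` (the default) for
#'   `floor(sqrt(n_cells))`.
#' @param nPCs Number of principal components (default 30).
#' @param nWindows Number of expression windows for the median
#'   correction (default 100).
#' @param nFeatures Number of features to select, or `"auto"` for the
#'   knee-point rule.
#' @param minDist Corrected-distance threshold applied in automatic
#'   selection mode (default 0.1).
#' @param seed Integer seed (default 0).
#' @param nullMode Null estimator, `"convolution"` or `"montecarlo"`.
#' @param nMC Monte-Carlo sample size (default 10000).
#' @param minCellsPerGene Minimum number of expressing cells for a gene
#'   to be scored (default 5).
#' @param includeSelf Add the center cell's count to its neighbor sum.
#' @param conditionNull Condition the null on an expressing center cell.
#' @param correction Window statistic, `"median"` or `"mean"`.
#' @param logNormalize Normalize and log1p before PCA.
#'
#' @return An [FSParam-class] object.
#' @examples
#' fsParam(k = 10, nFeatures = 250)
#' @export
fsParam <- function(k = "auto", nPCs = 30, nWindows = 100,
                    nFeatures = "auto", minDist = 0.1, seed = 0,
                    nullMode = c("convolution", "montecarlo"),
                    nMC = 10000, minCellsPerGene = 5,
                    includeSelf = TRUE, conditionNull = TRUE,
                    correction = c("median", "mean"),
                    logNormalize = TRUE) {
    toInt <- function(x) {
        if (identical(x, "auto")) NA_integer_ else as.integer(x)
    }
    new("FSParam",
        k = toInt(k), nPCs = as.integer(nPCs),
        nWindows = as.integer(nWindows), nFeatures = toInt(nFeatures),
        minDist = as.numeric(minDist), seed = as.integer(seed),
        nullMode = match.arg(nullMode), nMC = as.integer(nMC),
        minCellsPerGene = as.integer(minCellsPerGene),
        includeSelf = isTRUE(includeSelf),
        conditionNull = isTRUE(conditionNull),
        correction = match.arg(correction),
        logNormalize = isTRUE(logNormalize))
}

setMethod("show", "FSParam", function(object) {
    fmtInt <- function(x) if (is.na(x)) "auto" else as.character(x)
    cat("FSParam\n",
        "  k: ", fmtInt(object@k),
        "  nPCs: ", object@nPCs,
        "  nWindows: ", object@nWindows, "\n",
        "  nFeatures: ", fmtInt(object@nFeatures),
        "  minDist: ", object@minDist,
        "  seed: ", object@seed, "\n",
        "  null: ", object@nullMode,
        if (object@conditionNull) " (conditioned)" else " (unconditioned)",
        "  includeSelf: ", object@includeSelf,
        "  correction: ", object@correction, "\n", sep = "")
})

#' Nearest-neighbor graph of cells
#'
#' Stores, for each cell, the indices of its `k` nearest cells (self
#' excluded) in a reduced-dimension embedding, ordered by increasing
#' distance. The `includesSelf` flag records whether downstream
#' neighborhood sums add the center cell's own count, so that each sum
#' aggregates `k + 1` cells.
#'
#' @slot index Integer matrix, cells x k; row i holds the k nearest
#'   cells of cell i, nearest first.
#' @slot k Neighborhood size.
#' @slot includesSelf Whether neighborhood sums include the center cell.
#'
#' @export
setClass("NeighborGraph",
    representation(
        index = "matrix",
        k = "integer",
        includesSelf = "logical"
    )
)

setValidity("NeighborGraph", function(object) {
    idx <- object@index
    n <- nrow(idx)
    msg <- NULL
    if (ncol(idx) != object@k)
        msg <- c(msg, "'index' must have k columns")
    if (object@k > 0 && n > 0) {
        if (any(idx < 1L | idx > n))
            msg <- c(msg, "neighbor indices out of range")
        if (any(idx == row(idx)))
            msg <- c(msg, "a cell may not be its own listed neighbor")
        dup <- apply(idx, 1L, anyDuplicated)
        if (any(dup > 0))
            msg <- c(msg, "neighbor indices must be distinct within a row")
    }
    if (is.null(msg)) TRUE else msg
})

#' Accessors for NeighborGraph
#'
#' @param graph A [NeighborGraph-class] object.
#' @return `neighborIndex()` the cells x k integer index matrix;
#'   `neighborK()` the neighborhood size; `numCells()` the number of
#'   cells.
#' @export
neighborIndex <- function(graph) graph@index

#' @rdname neighborIndex
#' @export
numCells <- function(graph) nrow(graph@index)

#' @rdname neighborIndex
#' @export
neighborK <- function(graph) graph@k

setMethod("show", "NeighborGraph", function(object) {
    cat("NeighborGraph with ", nrow(object@index), " cells, k = ",
        object@k,
        if (object@includesSelf) " (+ self in sums)" else "",
        "\n", sep = "")
})

#' Probability mass function on a discrete support
#'
#' Carrier for the observed neighborhood-sum distribution of a gene and
#' for its null counterpart. The support is strictly increasing and the
#' mass sums to one.
#'
#' @slot support Strictly increasing numeric vector (non-negative
#'   counts, or non-negative reals for normalized data).
#' @slot mass Probabilities, same length as `support`.
#'
#' @seealso [discretePMF()], [wassersteinDistance()]
#' @export
setClass("DiscretePMF",
    representation(support = "numeric", mass = "numeric")
)

setValidity("DiscretePMF", function(object) {
    msg <- NULL
    if (length(object@support) != length(object@mass))
        msg <- c(msg, "'support' and 'mass' must have equal length")
    if (length(object@support) == 0L)
        msg <- c(msg, "empty PMF")
    if (any(diff(object@support) <= 0))
        msg <- c(msg, "'support' must be strictly increasing")
    if (any(object@mass < 0))
        msg <- c(msg, "'mass' must be non-negative")
    if (abs(sum(object@mass) - 1) > 1e-9)
        msg <- c(msg, "'mass' must sum to 1 (within 1e-9)")
    if (any(object@support < 0))
        msg <- c(msg, "'support' must be non-negative")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "DiscretePMF", function(object) {
    n <- length(object@support)
    cat("DiscretePMF on ", n, " support point", if (n != 1) "s", ", range [",
        object@support[1L], ", ", object@support[n], "]\n", sep = "")
})

#' Parameters of the splat-style count simulator
#'
#' The simulator draws gamma-distributed baseline gene means, applies
#' lognormal differential-expression factors per population with
#' probability `deProb`, draws lognormal library sizes and samples
#' counts from a Poisson with cell-specific rates, giving a
#' gamma-Poisson (negative-binomial-like) marginal.
#'
#' @slot nCells,nGenes,nPops Dataset dimensions.
#' @slot abundances Population proportions, summing to 1.
#' @slot deProb Probability that a (population, gene) pair receives a
#'   differential-expression factor.
#' @slot deFacLoc,deFacScale Lognormal location/scale of DE factors.
#' @slot meanShape,meanRate Gamma parameters of baseline gene means.
#' @slot libLoc,libScale Lognormal location/scale of library sizes.
#' @slot bcvCommon,bcvDF Biological coefficient of variation: each
#'   cell-gene Poisson rate is jittered by a gamma multiplier with
#'   CV `(bcvCommon + 1/sqrt(rate)) * sqrt(bcvDF / chi2_g)`, giving the
#'   negative-binomial-like overdispersion of UMI data. `bcvCommon = 0`
#'   disables the layer (pure Poisson).
#' @slot seed Integer seed.
#'
#' @seealso [simParam()], [simulateCounts()]
#' @export
setClass("SimParam",
    representation(
        nCells = "integer",
        nGenes = "integer",
        nPops = "integer",
        abundances = "numeric",
        deProb = "numeric",
        deFacLoc = "numeric",
        deFacScale = "numeric",
        meanShape = "numeric",
        meanRate = "numeric",
        libLoc = "numeric",
        libScale = "numeric",
        bcvCommon = "numeric",
        bcvDF = "numeric",
        seed = "integer"
    )
)

setValidity("SimParam", function(object) {
    msg <- NULL
    if (object@nCells < 1L || object@nGenes < 1L)
        msg <- c(msg, "'nCells' and 'nGenes' must be positive")
    if (length(object@abundances) != object@nPops)
        msg <- c(msg, "'abundances' must have one entry per population")
    if (abs(sum(object@abundances) - 1) > 1e-8)
        msg <- c(msg, "'abundances' must sum to 1")
    if (any(object@abundances <= 0))
        msg <- c(msg, "'abundances' must be positive")
    if (object@deProb <= 0 || object@deProb > 1)
        msg <- c(msg, "'deProb' must be in (0, 1]")
    if (object@meanShape <= 0 || object@meanRate <= 0)
        msg <- c(msg, "gamma parameters must be positive")
    if (object@bcvCommon < 0 || object@bcvDF <= 0)
        msg <- c(msg, "'bcvCommon' must be >= 0 and 'bcvDF' positive")
    if (is.null(msg)) TRUE else msg
})

#' Construct simulator parameters
#'
#' Defaults emulate the artificial benchmark design: 10,000 cells,
#' 15,000 genes and 9 populations with abundances
#' 25, 20, 15, 10, 10, 7, 5.5, 4 and 3.5 percent. Abundances may be
#' given as percentages (summing to 100) or proportions (summing to 1).
#'
#' @param nCells,nGenes Dataset dimensions.
#' @param abundances Population proportions or percentages.
#' @param deProb Differential-expression probability in (0, 1].
#' @param deFacLoc,deFacScale Lognormal DE-factor parameters.
#' @param meanShape,meanRate Gamma parameters of baseline gene means.
#' @param libLoc,libScale Lognormal library-size parameters; the
#'   defaults follow the splat model (`exp(11)`, about 60,000 counts
#'   per cell).
#' @param bcvCommon,bcvDF Overdispersion (biological coefficient of
#'   variation) parameters; see [SimParam-class]. Defaults 0.1 and 60.
#' @param seed Integer seed.
#'
#' @return A [SimParam-class] object.
#' @examples
#' simParam(nCells = 500, nGenes = 1000, deProb = 0.3, seed = 1)
#' @export
simParam <- function(nCells = 10000, nGenes = 15000,
                     abundances = c(25, 20, 15, 10, 10, 7, 5.5, 4, 3.5),
                     deProb = 0.1, deFacLoc = 0.1, deFacScale = 0.4,
                     meanShape = 0.6, meanRate = 0.3,
                     libLoc = 11, libScale = 0.2,
                     bcvCommon = 0.1, bcvDF = 60, seed = 0) {
    abundances <- as.numeric(abundances)
    if (abs(sum(abundances) - 100) < 1e-6)
        abundances <- abundances / 100
    new("SimParam",
        nCells = as.integer(nCells), nGenes = as.integer(nGenes),
        nPops = length(abundances), abundances = abundances,
        deProb = as.numeric(deProb), deFacLoc = as.numeric(deFacLoc),
        deFacScale = as.numeric(deFacScale),
        meanShape = as.numeric(meanShape), meanRate = as.numeric(meanRate),
        libLoc = as.numeric(libLoc), libScale = as.numeric(libScale),
        bcvCommon = as.numeric(bcvCommon), bcvDF = as.numeric(bcvDF),
        seed = as.integer(seed))
}

setMethod("show", "SimParam", function(object) {
    cat("SimParam: ", object@nCells, " cells x ", object@nGenes,
        " genes, ", object@nPops, " populations\n",
        "  deProb: ", object@deProb,
        "  seed: ", object@seed, "\n", sep = "")
})
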