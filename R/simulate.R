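#' Simulate a single-cell count matrix with known populations
#'
#' Splat-style gamma-Poisson generator. Baseline gene means are drawn
#' from a gamma distribution; each (population, gene) pair receives,
#' with probability `deProb`, a lognormal differential-expression
#' factor (up- or down-regulation with equal probability, downs as the
#' reciprocal of a lognormal draw); library sizes are lognormal; counts
#' are Poisson with rate `libSize * mu_g * f_pg / sum_g(mu_g)`,
#' jittered per cell and gene by a mean-1 gamma multiplier whose CV
#' follows the splat-style biological-coefficient-of-variation trend
#' (`bcvCommon + 1/sqrt(rate)`, modulated by a per-gene chi-square
#' draw), so marginal counts are gamma-Poisson (negative-binomial
#' like), as observed for UMI data. The common baseline normalizer
#' keeps non-DE genes at identical expected expression across
#' populations, so the stored DE factors are exact expected-mean
#' ratios.
#'
#' Population labels are assigned deterministically by largest-remainder
#' apportionment of the abundances, so population sizes are exact, not
#' stochastic.
#'
#' @param param A [SimParam-class].
#' @param chunkCells Number of cells sampled per block. Keeps peak
#'   memory bounded for large simulations; it takes part in the draw
#'   order, so reproducibility requires the same value along with the
#'   seed (the default is fixed).
#'
#' @return A [SingleCellExperiment::SingleCellExperiment] with a dense
#'   integer `"counts"` assay (genes x cells; at splat-model depths
#'   most entries are non-zero), `colData` columns
#'   `Population` (factor) and `LibSize`, `rowData` column `BaseMean`,
#'   and `metadata()` entries `deFactors` and `deFlags`
#'   (populations x genes), `popMeans` (exact expected mean count per
#'   population and gene), and `param`.
#' @examples
#' sim <- simulateCounts(simParam(nCells = 300, nGenes = 200, seed = 1))
#' table(sim$Population)
#' @export
simulateCounts <- function(param = simParam(), chunkCells = 1000L) {
    validObject(param)
    P <- param@nPops
    G <- param@nGenes
    N <- param@nCells

    sizes <- .largestRemainder(param@abundances, N)
    labels <- rep.int(seq_len(P), sizes)

    withr::with_seed(param@seed, {
        mu <- rgamma(G, shape = param@meanShape, rate = param@meanRate)
        deFlags <- matrix(rbinom(P * G, 1L, param@deProb) == 1L, P, G)
        fac <- matrix(1, P, G)
        nDE <- sum(deFlags)
        if (nDE > 0) {
            draw <- rlnorm(nDE, param@deFacLoc, param@deFacScale)
            down <- rbinom(nDE, 1L, 0.5) == 1L
            draw[down] <- 1 / draw[down]
            fac[deFlags] <- draw
        }
        libs <- rlnorm(N, param@libLoc, param@libScale)
        dfFac <- if (param@bcvCommon > 0)
            sqrt(param@bcvDF / stats::rchisq(G, df = param@bcvDF))
        else rep(1, G)

        ## expected count proportion per gene; common baseline
        ## normalizer across populations (see class docs)
        prop <- sweep(fac, 2L, mu / sum(mu), "*")

        ## counts held genes x cells as a dense integer matrix: at the
        ## library depths of the splat model more than half the entries
        ## are non-zero, so sparse triplets would cost more memory
        counts <- matrix(0L, G, N,
                         dimnames = list(sprintf("Gene%05d", seq_len(G)),
                                         sprintf("Cell%05d", seq_len(N))))
        for (start in seq(1L, N, by = chunkCells)) {
            cells <- start:min(start + chunkCells - 1L, N)
            lam <- libs[cells] * prop[labels[cells], , drop = FALSE]
            if (param@bcvCommon > 0) {
                bcv <- (param@bcvCommon + 1 / sqrt(pmax(lam, 1e-12))) *
                    rep(dfFac, each = length(cells))
                shp <- 1 / bcv^2
                lam <- rgamma(length(lam), shape = shp,
                              scale = as.vector(lam) / shp)
            }
            counts[, cells] <- t(matrix(rpois(length(lam), lam),
                                        nrow = length(cells)))
        }
    })

    expectedLib <- exp(param@libLoc + param@libScale^2 / 2)
    popMeans <- prop * expectedLib
    dimnames(popMeans) <- list(paste0("Pop", seq_len(P)), rownames(counts))
    dimnames(deFlags) <- dimnames(popMeans)
    dimnames(fac) <- dimnames(popMeans)

    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            Population = factor(paste0("Pop", labels),
                                levels = paste0("Pop", seq_len(P))),
            LibSize = libs,
            row.names = colnames(counts)),
        rowData = S4Vectors::DataFrame(BaseMean = mu,
                                       row.names = rownames(counts)),
        metadata = list(deFactors = fac, deFlags = deFlags,
                        popMeans = popMeans, param = param))
}

## deterministic largest-remainder apportionment of n among proportions
.largestRemainder <- function(prop, n) {
    quota <- prop * n
    sizes <- floor(quota)
    left <- n - sum(sizes)
    if (left > 0) {
        o <- order(-(quota - sizes), seq_along(prop), method = "radix")
        sizes[o[seq_len(left)]] <- sizes[o[seq_len(left)]] + 1
    }
    as.integer(sizes)
}

#' Exact expected expression per population and gene
#'
#' Returns the populations x genes matrix of expected mean counts used
#' by the sampler: `E[libSize] * mu_g * f_pg / sum_g(mu_g)`. Non-DE
#' genes have identical rows; for DE genes the between-population ratio
#' equals the stored DE factor exactly.
#'
#' @param sim A dataset from [simulateCounts()].
#' @return Numeric matrix, populations x genes.
#' @export
populationMeans <- function(sim) {
    pm <- S4Vectors::metadata(sim)$popMeans
    if (is.null(pm)) stop("'sim' was not produced by simulateCounts()")
    pm
}

#' Ground-truth differential-expression flags
#'
#' @param sim A dataset from [simulateCounts()].
#' @param union Collapse to a per-gene logical (`TRUE` if the gene is
#'   DE in any population)?
#' @return Logical populations x genes matrix, or a per-gene vector
#'   when `union = TRUE`.
#' @export
deFlags <- function(sim, union = FALSE) {
    fl <- S4Vectors::metadata(sim)$deFlags
    if (is.null(fl)) stop("'sim' was not produced by simulateCounts()")
    if (union) apply(fl, 2L, any) else fl
}

#' True population labels of a simulated dataset
#'
#' @param sim A dataset from [simulateCounts()].
#' @return Factor of population labels, one per cell.
#' @export
trueLabels <- function(sim) sim$Population
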