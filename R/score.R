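#' Observed neighborhood-sum distribution of a gene
#'
#' For every cell expressing the gene, the gene's counts are summed
#' over that cell's k nearest neighbors (plus the cell's own count when
#' the graph was built with `includeSelf = TRUE`). The empirical
#' distribution of these sums over expressing cells is the observed
#' distribution: a gene expressed by transcriptomically similar cells
#' yields larger sums than expected at random.
#'
#' @param x Numeric vector of the gene's counts, one entry per cell (in
#'   graph order).
#' @param graph A [NeighborGraph-class] built on the same cells.
#' @return A [DiscretePMF-class] of neighborhood sums.
#' @export
observedDistribution <- function(x, graph) {
    if (length(x) != numCells(graph))
        stop("'x' must have one count per cell in the graph")
    pos <- which(x > 0)
    if (length(pos) == 0L)
        stop(structure(
            class = c("knnfs_empty_distribution", "error", "condition"),
            list(message = "gene has no expressing cells",
                 call = sys.call())))
    k <- graph@k
    sums <- if (k > 0L) {
        idx <- graph@index[pos, , drop = FALSE]
        rowSums(matrix(x[idx], nrow = length(pos)))
    } else {
        numeric(length(pos))
    }
    if (graph@includesSelf) sums <- sums + x[pos]
    empiricalPMF(sums)
}

#' Null neighborhood-sum distribution of a gene
#'
#' The law of the same sum when the k cells are chosen at random, i.e.
#' without transcriptomic locality. In `"convolution"` mode (default)
#' this is computed exactly: the empirical per-cell PMF `P` of the gene
#' over all cells is convolved with itself k times, and — when the
#' observed statistic conditions on an expressing center cell with its
#' own count included — the result is further convolved with the PMF
#' `P+` over expressing cells only. In `"montecarlo"` mode the same law
#' is estimated from seeded random draws.
#'
#' With `conditioned = FALSE` the null is the plain k-fold convolution
#' of `P`, with no center-cell term.
#'
#' @param x Numeric vector of the gene's integer counts over all cells.
#' @param k Neighborhood size (>= 1; the center cell term is extra).
#' @param includeSelf Whether sums include the center cell's count.
#' @param conditioned Condition on an expressing center cell (default
#'   `TRUE`).
#' @param mode `"convolution"` (exact) or `"montecarlo"`.
#' @param nMC Number of Monte-Carlo draws.
#' @param seed Seed for Monte-Carlo mode.
#' @return A [DiscretePMF-class].
#' @export
nullDistribution <- function(x, k, includeSelf = TRUE, conditioned = TRUE,
                             mode = c("convolution", "montecarlo"),
                             nMC = 10000, seed = 0) {
    mode <- match.arg(mode)
    if (all(x == 0)) return(discretePMF(0, 1))
    if (mode == "convolution") {
        if (any(x != round(x)))
            stop("convolution null requires integer counts; ",
                 "use mode = 'montecarlo' for real-valued data")
        maxc <- max(x)
        n <- length(x)
        tab <- tabulate(x[x > 0], nbins = maxc)
        P <- discretePMF(0:maxc, c(n - sum(tab), tab) / n)
        base <- selfConvolvePMF(P, k)
        if (conditioned && includeSelf) {
            Pplus <- discretePMF(seq_len(maxc), tab / sum(tab))
            convolvePMF(Pplus, base)
        } else {
            base
        }
    } else {
        withr::with_seed(seed, {
            sums <- colSums(matrix(sample(x, nMC * k, replace = TRUE),
                                   nrow = k))
            if (conditioned && includeSelf) {
                xpos <- x[x > 0]
                sums <- sums + sample(xpos, nMC, replace = TRUE)
            }
            empiricalPMF(sums)
        })
    }
}

#' Score every gene by the Wasserstein distance to its null
#'
#' For each gene expressed in at least `minCellsPerGene` cells, computes
#' the observed neighborhood-sum distribution, its random-neighbor null,
#' and the 1-Wasserstein distance between them. Genes failing the filter
#' receive distance 0 and are excluded from the window correction and
#' from selection.
#'
#' @param counts Cells x genes counts (matrix, sparse Matrix or
#'   `SummarizedExperiment`).
#' @param graph A [NeighborGraph-class] on the same cells.
#' @param param An [FSParam-class].
#'
#' @return A [S4Vectors::DataFrame] with one row per gene: `geneId`,
#'   `meanExpr`, `nPositiveCells`, `rawDistance`, `scored`, and
#'   placeholder columns `window`, `correctedDistance`, `rank`,
#'   `selected` filled by [correctDistances()] and [rankAndSelect()].
#' @export
scoreGenes <- function(counts, graph, param = fsParam()) {
    m <- .asCellGene(counts)
    n <- nrow(m)
    if (n != numCells(graph))
        stop("graph and count matrix disagree on the number of cells")
    k <- graph@k

    ## neighborhood sums for all genes at once: one sparse matmul
    A <- Matrix::sparseMatrix(
        i = rep(seq_len(n), k), j = as.vector(graph@index),
        x = 1, dims = c(n, n))
    S <- A %*% m
    if (graph@includesSelf) S <- S + m
    S <- methods::as(S, "CsparseMatrix")

    nGenes <- ncol(m)
    mp <- m@p; mi <- m@i; mx <- m@x
    sp <- S@p; si <- S@i; sx <- S@x
    raw <- numeric(nGenes)
    npos <- integer(nGenes)
    meanExpr <- numeric(nGenes)
    scored <- logical(nGenes)

    for (j in seq_len(nGenes)) {
        if (mp[j + 1L] == mp[j]) next
        jj <- (mp[j] + 1L):mp[j + 1L]
        vals <- mx[jj]
        cells <- mi[jj] + 1L
        npos[j] <- length(vals)
        meanExpr[j] <- sum(vals) / n
        if (npos[j] < param@minCellsPerGene) next
        scored[j] <- TRUE

        ## observed sums over expressing cells
        scol <- numeric(n)
        sj <- (sp[j] + 1L):sp[j + 1L]
        if (sp[j + 1L] > sp[j]) scol[si[sj] + 1L] <- sx[sj]
        obs <- empiricalPMF(scol[cells])

        xj <- numeric(n)
        xj[cells] <- vals
        nul <- nullDistribution(
            xj, k, includeSelf = graph@includesSelf,
            conditioned = param@conditionNull, mode = param@nullMode,
            nMC = param@nMC, seed = param@seed + j)
        raw[j] <- wassersteinDistance(obs, nul)
    }

    S4Vectors::DataFrame(
        geneId = colnames(m),
        meanExpr = meanExpr,
        nPositiveCells = npos,
        rawDistance = raw,
        scored = scored,
        window = NA_integer_,
        correctedDistance = NA_real_,
        rank = NA_integer_,
        selected = FALSE,
        row.names = colnames(m))
}

#' Remove the expression-level trend from raw distances
#'
#' Raw Wasserstein distances grow with expression level. Scored genes
#' are binned into `w` equal-count windows by log mean expression, and
#' the window median (or mean) is subtracted from the distances in each
#' window, leaving a corrected distance comparable across expression
#' levels.
#'
#' @param table Gene score table from [scoreGenes()].
#' @param w Number of windows (>= 1, and at most the number of scored
#'   genes).
#' @param statistic `"median"` (default) or `"mean"`.
#' @return The table with `window` and `correctedDistance` filled in
#'   for scored genes.
#' @export
correctDistances <- function(table, w, statistic = c("median", "mean")) {
    statistic <- match.arg(statistic)
    w <- as.integer(w)
    sidx <- which(table$scored)
    if (length(sidx) == 0L) stop("no scored genes to correct")
    if (w < 1L) stop("'w' must be >= 1")
    if (w > length(sidx))
        stop("more windows (", w, ") than scored genes (",
             length(sidx), ")")
    lm <- log(table$meanExpr[sidx])
    o <- order(lm, sidx, method = "radix")
    win <- integer(length(sidx))
    win[o] <- ceiling(seq_along(o) * w / length(o))
    stat <- if (statistic == "median") stats::median else mean
    corrected <- numeric(length(sidx))
    for (b in seq_len(w)) {
        inb <- win == b
        corrected[inb] <- table$rawDistance[sidx][inb] -
            stat(table$rawDistance[sidx][inb])
    }
    table$window[sidx] <- win
    table$correctedDistance[sidx] <- corrected
    table
}

## knee of a decreasing curve y over x = 1..n: the point with maximum
## signed perpendicular distance *below* the chord joining the
## endpoints. Returns its index, or NA when the chord is degenerate.
.kneeIndex <- function(y) {
    n <- length(y)
    if (n < 3L || y[1L] == y[n]) return(NA_integer_)
    x <- seq_len(n)
    dx <- n - 1
    dy <- y[n] - y[1L]
    below <- (y[1L] - y) * dx + (x - 1) * dy
    if (max(below) <= 0) return(NA_integer_)
    which.max(below)
}

#' Rank corrected distances and select features
#'
#' Genes are ranked by decreasing corrected distance (ties broken by
#' gene identifier). With a numeric `nFeatures` the top-ranked prefix of
#' that size is selected. In automatic mode the cut-off is the knee of
#' the ranked curve — the point of maximum perpendicular distance below
#' the chord joining its endpoints — and the selection is the prefix
#' strictly before the knee, intersected with
#' `correctedDistance >= minDist`. When the curve is flat the knee is
#' undefined; a warning is emitted and only the `minDist` threshold is
#' applied.
#'
#' @param table Gene score table after [correctDistances()].
#' @param param An [FSParam-class]; `nFeatures` and `minDist` are
#'   honored.
#' @return The table with `rank` and `selected` filled in.
#' @export
rankAndSelect <- function(table, param = fsParam()) {
    sidx <- which(table$scored)
    if (length(sidx) == 0L) stop("no scored genes to rank")
    if (any(is.na(table$correctedDistance[sidx])))
        stop("corrected distances missing; run correctDistances() first")
    cd <- table$correctedDistance[sidx]
    o <- order(-cd, table$geneId[sidx], method = "radix")
    rk <- integer(length(sidx))
    rk[o] <- seq_along(o)
    table$rank[sidx] <- rk

    nSel <- param@nFeatures
    if (!is.na(nSel)) {
        nSel <- min(nSel, length(sidx))
        sel <- rk <= nSel
    } else {
        ySorted <- cd[o]
        knee <- .kneeIndex(ySorted)
        if (is.na(knee)) {
            warning("knee undefined (flat ranked curve); ",
                    "falling back to the minDist threshold")
            sel <- cd >= param@minDist
        } else {
            sel <- rk < knee & cd >= param@minDist
        }
    }
    table$selected <- logical(nrow(table))
    table$selected[sidx] <- sel
    table
}

#' Run the full feature-selection pipeline
#'
#' Composes graph construction, per-gene observed/null scoring, the
#' window correction and ranked selection. Fully deterministic for a
#' given seed and configuration.
#'
#' @param counts Cells x genes counts (matrix, sparse Matrix or
#'   `SummarizedExperiment`).
#' @param param An [FSParam-class].
#' @param verbose Emit progress messages.
#'
#' @return A gene score table ([S4Vectors::DataFrame]) whose metadata
#'   records the effective parameters; see [scoreGenes()] for columns.
#' @examples
#' sim <- simulateCounts(simParam(nCells = 200, nGenes = 100,
#'                                deProb = 0.3, seed = 1))
#' tbl <- selectFeatures(sim, fsParam(nWindows = 10, nFeatures = 20))
#' sum(tbl$selected)
#' @export
selectFeatures <- function(counts, param = fsParam(), verbose = FALSE) {
    m <- .asCellGene(counts)
    say <- function(...) if (verbose) message(...)
    say("building neighbor graph (", nrow(m), " cells, ",
        ncol(m), " genes)")
    graph <- buildNeighborGraph(m, param)
    say("k = ", graph@k, "; scoring genes")
    tbl <- scoreGenes(m, graph, param)
    w <- min(param@nWindows, sum(tbl$scored))
    tbl <- correctDistances(tbl, w, param@correction)
    tbl <- rankAndSelect(tbl, param)
    say(sum(tbl$selected), " genes selected")
    S4Vectors::metadata(tbl) <- list(
        param = param, k = graph@k, nCells = nrow(m), nGenes = ncol(m),
        nWindows = w, nScored = sum(tbl$scored),
        nSelected = sum(tbl$selected))
    tbl
}

#' Identifiers of the selected genes
#'
#' @param table A gene score table with the `selected` column filled.
#' @return Character vector of selected gene identifiers, in rank
#'   order.
#' @export
selectedGenes <- function(table) {
    sel <- which(table$selected)
    sel <- sel[order(table$rank[sel])]
    table$geneId[sel]
}
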