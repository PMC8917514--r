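#' @importFrom Matrix Diagonal rowSums colSums sparseMatrix t readMM writeMM
NULL

## Coerce supported containers to the internal convention: a sparse
## cells x genes matrix with cell and gene identifiers. Accepts a
## matrix / Matrix in cells x genes orientation, or a
## SummarizedExperiment / SingleCellExperiment whose "counts" assay is
## genes x cells (Bioconductor orientation) and is transposed on entry.
.asCellGene <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x, "counts")
        m <- Matrix::t(methods::as(m, "CsparseMatrix"))
    } else if (is.matrix(x)) {
        storage.mode(x) <- "double"
        m <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
    } else if (is(x, "Matrix")) {
        m <- methods::as(x, "CsparseMatrix")
    } else {
        stop("unsupported input of class '", class(x)[1L], "'")
    }
    if (any(m@x < 0)) stop("count matrix contains negative entries")
    if (is.null(rownames(m)))
        rownames(m) <- sprintf("Cell%05d", seq_len(nrow(m)))
    if (is.null(colnames(m)))
        colnames(m) <- sprintf("Gene%05d", seq_len(ncol(m)))
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
        stop("cell and gene identifiers must be unique")
    m
}

#' Library-size normalize and log-transform a count matrix
#'
#' Scales every cell to the median library size and applies
#' `log1p`. Zeros stay zero, so sparsity is preserved.
#'
#' @param counts Cells x genes matrix (dense or sparse), or a
#'   `SummarizedExperiment` with a genes x cells `"counts"` assay.
#' @return A sparse cells x genes matrix of log-normalized values.
#' @export
logNormalize <- function(counts) {
    m <- .asCellGene(counts)
    libs <- Matrix::rowSums(m)
    if (all(libs == 0)) stop("all-zero count matrix")
    sf <- stats::median(libs[libs > 0]) / libs
    sf[!is.finite(sf)] <- 0
    out <- Matrix::Diagonal(x = sf) %*% m
    out <- methods::as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(m)
    out
}

## Truncated PCA via an eigendecomposition of the smaller Gram matrix.
## Deterministic; column signs fixed so the largest-magnitude score in
## each component is positive.
.pcaScores <- function(x, nComp) {
    x <- as.matrix(x)
    n <- nrow(x)
    nComp <- min(nComp, n - 1L, ncol(x))
    cm <- colMeans(x)
    xc <- sweep(x, 2L, cm)
    if (n <= ncol(x)) {
        g <- tcrossprod(xc)
        ee <- eigen(g, symmetric = TRUE)
        d2 <- pmax(ee$values[seq_len(nComp)], 0)
        scores <- ee$vectors[, seq_len(nComp), drop = FALSE] %*%
            diag(sqrt(d2), nComp)
    } else {
        g <- crossprod(xc)
        ee <- eigen(g, symmetric = TRUE)
        v <- ee$vectors[, seq_len(nComp), drop = FALSE]
        scores <- xc %*% v
    }
    for (j in seq_len(ncol(scores))) {
        i <- which.max(abs(scores[, j]))
        if (scores[i, j] < 0) scores[, j] <- -scores[, j]
    }
    scores
}

## Exact k-nearest neighbors by Euclidean distance, computed blockwise.
## Ties are broken by the lower cell index; self is excluded. Rows come
## back ordered by increasing distance.
.knnExact <- function(scores, k, block = 1024L) {
    n <- nrow(scores)
    if (k >= n) stop("'k' must be smaller than the number of cells")
    sq <- rowSums(scores^2)
    idx <- matrix(0L, n, k)
    for (start in seq(1L, n, by = block)) {
        rows <- start:min(start + block - 1L, n)
        d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(
            scores[rows, , drop = FALSE], scores)
        for (ii in seq_along(rows)) {
            d <- d2[ii, ]
            d[rows[ii]] <- Inf
            o <- order(d, seq_len(n), method = "radix")
            idx[rows[ii], ] <- o[seq_len(k)]
        }
    }
    idx
}

#' Build the k-nearest-neighbor graph of cells
#'
#' Normalizes the counts (library-size scaling plus `log1p`, unless
#' disabled), computes a truncated PCA and links every cell to its `k`
#' nearest cells by Euclidean distance in PC space using an exact
#' search. With `k = "auto"` (via the parameter object),
#' `k = floor(sqrt(n_cells))`.
#'
#' @param counts Cells x genes counts (matrix, sparse Matrix, or
#'   `SummarizedExperiment`).
#' @param param An [FSParam-class]; `k`, `nPCs`, `includeSelf` and
#'   `logNormalize` are honored.
#'
#' @return A [NeighborGraph-class].
#' @examples
#' m <- matrix(rpois(600, 2), 30, 20)
#' buildNeighborGraph(m, fsParam(k = 5, nPCs = 5))
#' @export
buildNeighborGraph <- function(counts, param = fsParam()) {
    m <- .asCellGene(counts)
    n <- nrow(m)
    k <- param@k
    if (is.na(k)) k <- as.integer(floor(sqrt(n)))
    if (n < k + 1L)
        stop("need at least k + 1 = ", k + 1L, " cells, got ", n)
    if (sum(m@x) == 0) stop("all-zero count matrix")
    ln <- if (param@logNormalize) logNormalize(m) else m
    scores <- .pcaScores(ln, param@nPCs)
    idx <- .knnExact(scores, k)
    new("NeighborGraph", index = idx, k = as.integer(k),
        includesSelf = param@includeSelf)
}
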