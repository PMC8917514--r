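#' KNN-smooth expression values
#'
#' Replaces each cell's value of each gene by the mean of that gene's
#' counts over the cell's k nearest neighbors (self excluded by
#' default), reducing the noisiness of sparse expression before marker
#' scoring.
#'
#' @param counts Cells x genes matrix (typically restricted to marker
#'   genes).
#' @param graph A [NeighborGraph-class] on the same cells.
#' @param includeSelf Also average in the cell's own count (divisor
#'   becomes `k + 1`).
#' @return Dense cells x genes matrix of smoothed values.
#' @export
knnSmooth <- function(counts, graph, includeSelf = FALSE) {
    m <- .asCellGene(counts)
    n <- nrow(m)
    if (n != numCells(graph))
        stop("graph and count matrix disagree on the number of cells")
    k <- graph@k
    A <- Matrix::sparseMatrix(
        i = rep(seq_len(n), k), j = as.vector(graph@index),
        x = 1, dims = c(n, n))
    out <- if (includeSelf) (A %*% m + m) / (k + 1) else (A %*% m) / k
    out <- as.matrix(out)
    dimnames(out) <- dimnames(m)
    out
}

#' Rank-normalize a vector to (0, 1]
#'
#' Values are replaced by their ascending rank (average rank for ties)
#' divided by the vector length, so the highest-expressing cell maps
#' to 1. Invariant under monotone transformations of the input.
#'
#' @param values Numeric vector.
#' @return Numeric vector in `(0, 1]`.
#' @examples
#' rankNormalize(c(5, 1, 3))  # 1, 1/3, 2/3
#' @export
rankNormalize <- function(values) {
    if (length(values) == 0L) stop("empty vector")
    rank(values, ties.method = "average") / length(values)
}

#' Per-cell marker scores for a set of labels
#'
#' For each label, the marker genes' smoothed expression is
#' rank-normalized across cells and averaged over the label's markers,
#' giving one score per cell and label.
#'
#' @param counts Cells x genes counts.
#' @param markers Named list; each element a character vector of marker
#'   gene identifiers for that label.
#' @param graph A [NeighborGraph-class] used for smoothing; built
#'   automatically (with `k = floor(sqrt(n))`) when `NULL`.
#' @param smoothIncludeSelf Passed to [knnSmooth()].
#' @return Cells x labels numeric matrix with entries in `(0, 1]`.
#' @export
labelScores <- function(counts, markers, graph = NULL,
                        smoothIncludeSelf = FALSE) {
    m <- .asCellGene(counts)
    if (is.null(names(markers)) || anyDuplicated(names(markers)))
        stop("'markers' must be a uniquely named list")
    markers <- lapply(markers, function(g) {
        keep <- g %in% colnames(m)
        if (!all(keep))
            warning(sum(!keep), " marker(s) not found in the matrix ",
                    "and dropped")
        g[keep]
    })
    if (any(lengths(markers) == 0L))
        stop("label(s) without resolvable markers: ",
             paste(names(markers)[lengths(markers) == 0L],
                   collapse = ", "))
    if (is.null(graph))
        graph <- buildNeighborGraph(m, fsParam())
    allMk <- unique(unlist(markers))
    sm <- knnSmooth(m[, allMk, drop = FALSE], graph,
                    includeSelf = smoothIncludeSelf)
    rn <- apply(sm, 2L, rankNormalize)
    out <- vapply(markers, function(g)
        rowMeans(rn[, g, drop = FALSE]), numeric(nrow(m)))
    rownames(out) <- rownames(m)
    out
}

#' Percentile score of each label within each cluster
#'
#' Aggregates per-cell label scores to one number per (cluster, label):
#' the given percentile (linear interpolation between order statistics)
#' of the label's scores among the cluster's cells.
#'
#' @param cellScores Cells x labels matrix from [labelScores()].
#' @param clusters Cluster labels, one per cell.
#' @param percentile Percentile in (0, 100); default 70.
#' @return Clusters x labels matrix with entries in `[0, 1]`.
#' @export
scoreClusters <- function(cellScores, clusters, percentile = 70) {
    if (percentile <= 0 || percentile >= 100)
        stop("'percentile' must be in (0, 100)")
    clusters <- as.factor(clusters)
    if (length(clusters) != nrow(cellScores))
        stop("one cluster label per cell required")
    if (any(table(clusters) == 0L)) stop("empty cluster")
    out <- matrix(0, nlevels(clusters), ncol(cellScores),
                  dimnames = list(levels(clusters),
                                  colnames(cellScores)))
    for (g in levels(clusters)) {
        out[g, ] <- apply(cellScores[clusters == g, , drop = FALSE], 2L,
                          quantile, probs = percentile / 100,
                          names = FALSE)
    }
    out
}

#' Assign labels to clusters from a score matrix
#'
#' Each cluster receives the label with the highest score. With
#' `allowIntermediate = TRUE`, labels whose score is within
#' `mergeThreshold` of the maximum are merged into a composite label
#' (joined with `"+"`, best first). All-zero rows are labeled
#' `"unassigned"`.
#'
#' @param scoreMatrix Clusters x labels matrix from [scoreClusters()].
#' @param mergeThreshold Maximum score difference for merging (default
#'   0.05).
#' @param allowIntermediate Allow composite labels.
#' @return A `data.frame` with columns `cluster`, `label`, `score`.
#' @export
assignLabels <- function(scoreMatrix, mergeThreshold = 0.05,
                         allowIntermediate = FALSE) {
    labs <- colnames(scoreMatrix)
    if (is.null(labs)) labs <- paste0("Label", seq_len(ncol(scoreMatrix)))
    res <- lapply(seq_len(nrow(scoreMatrix)), function(i) {
        row <- scoreMatrix[i, ]
        if (all(row == 0))
            return(data.frame(cluster = rownames(scoreMatrix)[i],
                              label = "unassigned", score = 0))
        top <- max(row)
        members <- if (allowIntermediate)
            which(top - row <= mergeThreshold) else which.max(row)
        o <- order(-row[members], labs[members], method = "radix")
        data.frame(cluster = rownames(scoreMatrix)[i],
                   label = paste(labs[members][o], collapse = "+"),
                   score = top)
    })
    do.call(rbind, res)
}

#' Match clusters to marker-defined cell-type labels
#'
#' End-to-end population matching: smooth marker expression over the
#' KNN graph, rank-normalize, average per label, take the per-cluster
#' percentile and assign each cluster the best-scoring label (with
#' optional intermediate composite labels).
#'
#' @inheritParams labelScores
#' @param clusters Precomputed cluster labels, one per cell (e.g. from
#'   high-resolution Leiden clustering).
#' @param percentile Percentile used by [scoreClusters()] (default 70).
#' @param mergeThreshold,allowIntermediate See [assignLabels()].
#' @return A list with `assignment` (data.frame) and `scoreMatrix`.
#' @export
matchPopulations <- function(counts, clusters, markers, graph = NULL,
                             percentile = 70, mergeThreshold = 0.05,
                             allowIntermediate = FALSE,
                             smoothIncludeSelf = FALSE) {
    cs <- labelScores(counts, markers, graph,
                      smoothIncludeSelf = smoothIncludeSelf)
    sm <- scoreClusters(cs, clusters, percentile)
    list(assignment = assignLabels(sm, mergeThreshold, allowIntermediate),
         scoreMatrix = sm)
}

#' Read marker lists from TSV or JSON
#'
#' TSV format: two tab-separated columns, label and a comma-joined list
#' of marker genes, no header. JSON format: an object mapping label
#' names to arrays of gene identifiers.
#'
#' @param path File path (`.json` files are parsed as JSON, anything
#'   else as TSV).
#' @return Named list of character vectors.
#' @export
readMarkers <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        mk <- jsonlite::read_json(path, simplifyVector = TRUE)
        return(lapply(mk, as.character))
    }
    d <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character")
    if (ncol(d) < 2L) stop("marker TSV needs two columns: label, genes")
    out <- lapply(d[[2L]], function(s) trimws(strsplit(s, ",")[[1L]]))
    names(out) <- d[[1L]]
    out
}
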