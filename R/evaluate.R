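#' Normalized mutual information between two labelings
#'
#' `NMI(T, L) = 2 I(T; L) / (H(T) + H(L))`, computed from the
#' contingency table with natural logarithms (the base cancels).
#' Symmetric, invariant to relabeling, 1 for identical partitions. When
#' both labelings are a single constant class both entropies vanish and
#' the value is defined as 1 (degenerate perfect agreement).
#'
#' @param t,l Label vectors of equal length (any atomic type or
#'   factor).
#' @return Numeric in `[0, 1]`.
#' @examples
#' nmi(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
nmi <- function(t, l) {
    ct <- .contingency(t, l)
    n <- sum(ct)
    pij <- ct / n
    pi_ <- rowSums(pij)
    p_j <- colSums(pij)
    ht <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
    hl <- -sum(ifelse(p_j > 0, p_j * log(p_j), 0))
    if (ht + hl == 0) return(1)
    e <- outer(pi_, p_j)
    nz <- pij > 0
    mi <- sum(pij[nz] * log(pij[nz] / e[nz]))
    2 * mi / (ht + hl)
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement corrected for chance:
#' `(RI - E[RI]) / (max(RI) - E[RI])` in the standard contingency-table
#' form. 1 for identical partitions, ~0 for random ones.
#'
#' @inheritParams nmi
#' @return Numeric in `(-1, 1]`.
#' @export
ari <- function(t, l) {
    ct <- .contingency(t, l)
    n <- sum(ct)
    sumij <- sum(choose(ct, 2))
    a <- sum(choose(rowSums(ct), 2))
    b <- sum(choose(colSums(ct), 2))
    expected <- a * b / choose(n, 2)
    maxidx <- (a + b) / 2
    if (maxidx == expected) return(1)  # both partitions trivial
    (sumij - expected) / (maxidx - expected)
}

.contingency <- function(t, l) {
    if (length(t) != length(l))
        stop("label vectors must have equal length")
    if (length(t) == 0L) stop("empty label vectors")
    table(as.character(t), as.character(l))
}

#' Mean silhouette coefficient under cosine distance
#'
#' For each cell `c` in cluster `Ci`, `a(c)` is the mean cosine distance
#' to the other members of `Ci` and `b(c)` the minimum over other
#' clusters of the mean distance to that cluster's members;
#' `s(c) = (b - a) / max(a, b)`. Cells in singleton clusters get
#' `s(c) = 0`. The score is the mean of `s(c)` over all cells, computed
#' on the expression of the supplied (typically selected) genes.
#'
#' @param expr Cells x genes numeric matrix (dense or sparse),
#'   restricted to the genes of interest.
#' @param labels Cluster labels, one per cell; at least two distinct
#'   clusters required.
#' @return Numeric in `[-1, 1]`.
#' @export
silhouetteScore <- function(expr, labels) {
    x <- as.matrix(expr)
    labels <- as.character(labels)
    if (nrow(x) != length(labels))
        stop("one label per cell required")
    cl <- unique(labels)
    if (length(cl) < 2L)
        stop("silhouette is undefined for a single cluster")
    nrm <- sqrt(rowSums(x^2))
    nrm[nrm == 0] <- 1  # zero vectors: treated as orthogonal to all
    xn <- x / nrm
    D <- 1 - tcrossprod(xn)
    n <- nrow(x)
    sizes <- table(labels)[cl]
    ## mean distance from every cell to every cluster
    M <- vapply(cl, function(g)
        rowSums(D[, labels == g, drop = FALSE]), numeric(n))
    s <- numeric(n)
    for (i in seq_len(n)) {
        g <- match(labels[i], cl)
        szg <- sizes[[g]]
        if (szg == 1L) { s[i] <- 0; next }
        a <- M[i, g] / (szg - 1)  # exclude self (self-distance is 0)
        b <- min(M[i, -g] / as.numeric(sizes[-g]))
        s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    mean(s)
}

#' Jaccard index between two gene sets
#'
#' `|a intersect b| / |a union b|`; 0 when both sets are empty.
#'
#' @param a,b Character vectors (treated as sets).
#' @return Numeric in `[0, 1]`.
#' @export
jaccardIndex <- function(a, b) {
    u <- union(a, b)
    if (length(u) == 0L) return(0)
    length(intersect(a, b)) / length(u)
}

#' Proportion of ribosomal and mitochondrial genes selected
#'
#' Ribosomal genes are those whose identifier starts with `RPS` or
#' `RPL`, mitochondrial genes those starting with `MT-`
#' (case-insensitive). The default denominator is the number of such
#' genes present in the dataset; `denominator = "selected"` instead
#' reports the share of the selection that is ribosomal/mitochondrial.
#'
#' @param geneIds All gene identifiers in the dataset.
#' @param selected Identifiers of the selected genes.
#' @param denominator `"list"` (default; share of the prefixed genes
#'   that got selected) or `"selected"`.
#' @return Named numeric vector `c(ribo = , mito = )`, in percent.
#' @export
riboMitoProportion <- function(geneIds, selected,
                               denominator = c("list", "selected")) {
    denominator <- match.arg(denominator)
    isRibo <- grepl("^RP[SL]", geneIds, ignore.case = TRUE)
    isMito <- grepl("^MT-", geneIds, ignore.case = TRUE)
    inSel <- geneIds %in% selected
    pct <- function(num, den, what) {
        if (den == 0L) {
            warning("no ", what, " genes in the ",
                    if (denominator == "list") "dataset" else "selection")
            return(0)
        }
        100 * num / den
    }
    if (denominator == "list") {
        c(ribo = pct(sum(isRibo & inSel), sum(isRibo), "ribosomal"),
          mito = pct(sum(isMito & inSel), sum(isMito), "mitochondrial"))
    } else {
        c(ribo = pct(sum(isRibo & inSel), sum(inSel), "selected"),
          mito = pct(sum(isMito & inSel), sum(inSel), "selected"))
    }
}

#' Ranked per-cluster expression-proportion profile
#'
#' For each gene, expression is scaled to sum to 1 over all cells, the
#' per-cluster proportions are computed and sorted in decreasing order;
#' the profile is the mean of these sorted vectors over the gene set. A
#' locally expressed gene set concentrates near 1 in the first entry.
#'
#' @param counts Cells x genes counts.
#' @param clusters Cluster labels, one per cell.
#' @param genes Gene identifiers to profile.
#' @return Numeric vector of length `nlevels(clusters)`, decreasing,
#'   summing to 1.
#' @export
expressionLocality <- function(counts, clusters, genes) {
    m <- .asCellGene(counts)
    clusters <- as.factor(clusters)
    if (nrow(m) != length(clusters)) stop("one cluster label per cell")
    genes <- intersect(genes, colnames(m))
    if (length(genes) == 0L) stop("no requested genes in the matrix")
    sub <- m[, genes, drop = FALSE]
    tot <- Matrix::colSums(sub)
    if (any(tot == 0)) {
        warning(sum(tot == 0), " gene(s) with zero total counts excluded")
        sub <- sub[, tot > 0, drop = FALSE]
        tot <- tot[tot > 0]
        if (length(tot) == 0L) stop("all requested genes are silent")
    }
    agg <- rowsum(as.matrix(sub), droplevels(clusters))  # clusters x genes
    prop <- sweep(agg, 2L, tot, "/")
    ranked <- apply(prop, 2L, sort, decreasing = TRUE)
    rowMeans(matrix(ranked, nrow = nrow(agg)))
}

#' Baseline feature selectors
#'
#' Reference selectors for benchmarking: `"std"` ranks genes by the
#' standard deviation of their log-normalized expression; `"dispersion"`
#' by the within-mean-bin z-score of the variance/mean ratio of
#' normalized expression (the classic highly-variable-gene recipe);
#' `"random"` draws a seeded uniform sample of genes.
#'
#' @param method One of `"std"`, `"dispersion"`, `"random"`.
#' @param counts Cells x genes counts.
#' @param n Number of genes to select.
#' @param seed Seed for `"random"`.
#' @param nBins Mean-expression bins for `"dispersion"` (default 20).
#' @return Character vector of `n` gene identifiers.
#' @export
baselineSelect <- function(method = c("std", "dispersion", "random"),
                           counts, n, seed = 0, nBins = 20) {
    method <- match.arg(method)
    m <- .asCellGene(counts)
    if (n > ncol(m)) stop("'n' exceeds the number of genes")
    ids <- colnames(m)
    if (method == "random")
        return(withr::with_seed(seed, sample(ids, n)))
    if (method == "std") {
        ln <- logNormalize(m)
        mu <- Matrix::colSums(ln) / nrow(ln)
        ex2 <- Matrix::colSums(ln^2) / nrow(ln)
        sdv <- sqrt(pmax(ex2 - mu^2, 0) * nrow(ln) / (nrow(ln) - 1))
        o <- order(-sdv, ids, method = "radix")
        return(ids[o[seq_len(n)]])
    }
    ## dispersion: var/mean of library-size-normalized counts, z-scored
    ## within equal-count bins of mean expression
    libs <- Matrix::rowSums(m)
    sf <- stats::median(libs[libs > 0]) / pmax(libs, 1)
    nm <- Matrix::Diagonal(x = sf) %*% m
    mu <- Matrix::colSums(nm) / nrow(nm)
    ex2 <- Matrix::colSums(nm^2) / nrow(nm)
    v <- pmax(ex2 - mu^2, 0) * nrow(nm) / (nrow(nm) - 1)
    disp <- ifelse(mu > 0, v / mu, 0)
    bin <- integer(length(mu))
    o <- order(mu, seq_along(mu), method = "radix")
    bin[o] <- ceiling(seq_along(o) * nBins / length(o))
    z <- numeric(length(disp))
    for (b in unique(bin)) {
        inb <- bin == b
        s <- stats::sd(disp[inb])
        z[inb] <- if (is.na(s) || s == 0) 0 else
            (disp[inb] - mean(disp[inb])) / s
    }
    o <- order(-z, ids, method = "radix")
    ids[o[seq_len(n)]]
}

#' Leiden clustering matched to a target number of communities
#'
#' Builds an undirected graph from the KNN index and runs Leiden
#' community detection (modularity objective), bisecting the resolution
#' parameter until the number of communities equals `targetK` (at most
#' `maxIter` bisection steps; the closest count is returned when an
#' exact match is not reached).
#'
#' @param graph A [NeighborGraph-class].
#' @param targetK Desired number of communities.
#' @param seed Seed for the Leiden refinement.
#' @param maxIter Bisection iterations (default 20).
#' @return Integer membership vector (one entry per cell) with
#'   attributes `resolution` and `nCommunities`.
#' @export
clusterToK <- function(graph, targetK, seed = 0, maxIter = 20) {
    idx <- neighborIndex(graph)
    n <- nrow(idx)
    el <- cbind(rep(seq_len(n), ncol(idx)), as.vector(idx))
    g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
    runAt <- function(res) {
        memb <- withr::with_seed(seed, igraph::membership(
            igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = res, n_iterations = 3)))
        as.integer(memb)
    }
    evalRes <- function(res) {
        memb <- runAt(res)
        list(res = res, memb = memb, k = length(unique(memb)))
    }
    lo <- evalRes(1e-4)
    hi <- evalRes(1)
    tries <- 0L
    while (hi$k < targetK && tries < 12L) {
        hi <- evalRes(hi$res * 2)
        tries <- tries + 1L
    }
    best <- if (abs(lo$k - targetK) <= abs(hi$k - targetK)) lo else hi
    for (i in seq_len(maxIter)) {
        if (best$k == targetK) break
        mid <- evalRes((lo$res + hi$res) / 2)
        if (abs(mid$k - targetK) < abs(best$k - targetK)) best <- mid
        if (mid$k < targetK) lo <- mid else hi <- mid
        if (hi$res - lo$res < 1e-6) break
    }
    structure(best$memb, resolution = best$res, nCommunities = best$k)
}

#' Population-recovery benchmark on simulated data
#'
#' For each seed, simulates a dataset, selects `nFeatures` genes with
#' each method, rebuilds the neighbor graph on the selected submatrix
#' (30 PCs, `k = floor(sqrt(n))`), runs Leiden at the resolution
#' matching the true number of populations and scores the communities
#' against the ground-truth labels with NMI and ARI.
#'
#' @param param A [SimParam-class]; its seed is the base seed, shifted
#'   by the run index.
#' @param methods Subset of `c("knnfs", "std", "dispersion", "random")`.
#' @param nFeatures Number of genes each selector keeps (default 250).
#' @param nSeeds Number of simulated replicates (default 5).
#' @param fsparam [FSParam-class] used by the `"knnfs"` selector.
#' @param verbose Emit per-run progress messages.
#' @return A `data.frame` with one row per (seed, method):
#'   `seed`, `method`, `nmi`, `ari`, `nCommunities`.
#' @export
recoveryExperiment <- function(param,
                               methods = c("knnfs", "std", "dispersion",
                                           "random"),
                               nFeatures = 250, nSeeds = 5,
                               fsparam = fsParam(), verbose = FALSE) {
    methods <- match.arg(methods, several.ok = TRUE)
    rows <- list()
    for (s in seq_len(nSeeds)) {
        sp <- param
        sp@seed <- param@seed + s - 1L
        sim <- simulateCounts(sp)
        m <- .asCellGene(sim)
        truth <- trueLabels(sim)
        for (meth in methods) {
            if (verbose) message("seed ", sp@seed, ": ", meth)
            genes <- if (meth == "knnfs") {
                fp <- fsparam
                fp@nFeatures <- as.integer(nFeatures)
                fp@seed <- sp@seed
                selectedGenes(selectFeatures(m, fp))
            } else {
                baselineSelect(meth, m, nFeatures, seed = sp@seed)
            }
            sub <- m[, genes, drop = FALSE]
            g <- buildNeighborGraph(sub, fsParam(seed = sp@seed))
            memb <- clusterToK(g, param@nPops, seed = sp@seed)
            rows[[length(rows) + 1L]] <- data.frame(
                seed = sp@seed, method = meth,
                nmi = nmi(truth, memb), ari = ari(truth, memb),
                nCommunities = attr(memb, "nCommunities"))
        }
    }
    do.call(rbind, rows)
}

#' Summarize a recovery experiment per method
#'
#' @param results Output of [recoveryExperiment()].
#' @return A `data.frame` with mean and sd of NMI and ARI per method,
#'   sorted by decreasing mean NMI.
#' @export
summarizeRecovery <- function(results) {
    agg <- lapply(split(results, results$method), function(d)
        data.frame(method = d$method[1L],
                   meanNMI = mean(d$nmi), sdNMI = stats::sd(d$nmi),
                   meanARI = mean(d$ari), sdARI = stats::sd(d$ari),
                   n = nrow(d)))
    out <- do.call(rbind, agg)
    out[order(-out$meanNMI), , drop = FALSE]
}
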