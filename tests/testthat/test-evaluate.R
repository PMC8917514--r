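test_that("nmi matches hand-computed and oracle values", {
    expect_equal(nmi(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
    ## independent partitions: zero mutual information
    expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
    ## degenerate: both constant
    expect_equal(nmi(rep(1, 5), rep("x", 5)), 1)
    set.seed(3)
    for (i in 1:20) {
        n <- sample(4:12, 1)
        t <- sample(1:3, n, replace = TRUE)
        l <- sample(1:4, n, replace = TRUE)
        expect_equal(nmi(t, l), oracleNMI(t, l), tolerance = 1e-12)
        expect_equal(nmi(t, l), nmi(l, t), tolerance = 1e-12)
        ## invariance under relabeling
        perm <- sample(10:13)
        expect_equal(nmi(perm[t], l), nmi(t, l), tolerance = 1e-12)
    }
})

test_that("nmi agrees with igraph's implementation", {
    set.seed(9)
    t <- sample(1:4, 200, replace = TRUE)
    l <- sample(1:3, 200, replace = TRUE)
    expect_equal(nmi(t, l), igraph::compare(t, l, method = "nmi"),
                 tolerance = 1e-12)
})

test_that("ari matches pair-counting oracle and mclust", {
    expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
    ## crossed 2x2 partitions (checked against scikit-learn's
    ## adjusted_rand_score and the contingency formula)
    expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
    set.seed(5)
    for (i in 1:20) {
        n <- sample(5:12, 1)
        t <- sample(1:3, n, replace = TRUE)
        l <- sample(1:3, n, replace = TRUE)
        if (length(unique(t)) == 1 && length(unique(l)) == 1) next
        expect_equal(ari(t, l), oracleARI(t, l), tolerance = 1e-12)
        expect_equal(ari(t, l), mclust::adjustedRandIndex(t, l),
                     tolerance = 1e-12)
        expect_equal(ari(t, l), ari(l, t), tolerance = 1e-12)
    }
    ## random labelings have expected ARI about 0
    set.seed(8)
    t <- sample(1:4, 60, replace = TRUE)
    vals <- replicate(1000, ari(t, sample(t)))
    expect_lt(abs(mean(vals)), 0.02)
})

test_that("silhouette matches the brute-force double loop", {
    set.seed(21)
    x <- matrix(rgamma(50 * 8, 2), 50, 8)
    labels <- sample(1:4, 50, replace = TRUE)
    expect_equal(silhouetteScore(x, labels), oracleSilhouette(x, labels),
                 tolerance = 1e-12)
    ## orthogonal identical clusters: perfect separation
    y <- rbind(matrix(rep(c(1, 0), each = 10), 10, 2),
               matrix(rep(c(0, 1), each = 10), 10, 2))
    expect_equal(silhouetteScore(y, rep(1:2, each = 10)), 1)
    ## shuffled labels: near zero
    set.seed(22)
    z <- matrix(rgamma(500 * 10, 2), 500, 10)
    expect_lt(abs(silhouetteScore(z, sample(1:4, 500, replace = TRUE))),
              0.05)
    expect_gte(min(replicate(5, silhouetteScore(
        x, sample(labels)))), -1)
    expect_error(silhouetteScore(x, rep(1, 50)), "single cluster")
})

test_that("silhouette agrees with the cluster package under cosine distance", {
    set.seed(33)
    x <- matrix(rgamma(40 * 6, 2), 40, 6)
    labels <- rep(1:3, length.out = 40)
    xn <- x / sqrt(rowSums(x^2))
    D <- stats::as.dist(1 - tcrossprod(xn))
    ref <- mean(cluster::silhouette(labels, D)[, "sil_width"])
    expect_equal(silhouetteScore(x, labels), ref, tolerance = 1e-9)
})

test_that("jaccard index follows the set definition", {
    expect_equal(jaccardIndex(c("a", "b"), c("a", "b")), 1)
    expect_equal(jaccardIndex("a", "b"), 0)
    expect_equal(jaccardIndex(c("a", "b", "c"), c("b", "c", "d")), 0.5)
    expect_equal(jaccardIndex(character(), character()), 0)
})

test_that("ribosomal/mitochondrial proportions use the prefix rule", {
    ids <- c("RPS6", "RPL3", "MT-CO1", "ACTB")
    expect_equal(riboMitoProportion(ids, c("RPS6", "ACTB")),
                 c(ribo = 50, mito = 0))
    expect_equal(riboMitoProportion(ids, ids), c(ribo = 100, mito = 100))
    expect_equal(riboMitoProportion(ids, "ACTB"), c(ribo = 0, mito = 0))
    ## case-insensitive prefixes, and warning when no prefixed genes
    expect_equal(riboMitoProportion(c("rps1", "Rpl2", "mt-nd1", "B"),
                                    c("rps1", "mt-nd1")),
                 c(ribo = 50, mito = 100))
    w <- capture_warnings(riboMitoProportion(c("AA", "BB"), "AA"))
    expect_match(w, "ribosomal", all = FALSE)
    expect_match(w, "mitochondrial", all = FALSE)
    ## alternative denominator: share of the selection
    expect_equal(
        riboMitoProportion(ids, c("RPS6", "ACTB"),
                           denominator = "selected"),
        c(ribo = 50, mito = 0))
})

test_that("expression locality profiles behave as designed", {
    m <- matrix(0, 4, 2, dimnames = list(paste0("c", 1:4), c("g1", "g2")))
    m[, 1] <- c(3, 1, 0, 0)   # concentrated in cluster A
    m[, 2] <- c(1, 1, 1, 1)   # uniform
    cl <- c("A", "A", "B", "B")
    expect_equal(expressionLocality(m, cl, "g1"), c(1, 0))
    expect_equal(expressionLocality(m, cl, "g2"), c(0.5, 0.5))
    expect_warning(
        expressionLocality(cbind(m, g3 = 0), cl, c("g1", "g3")),
        "zero total")
})

test_that("baseline selectors rank by their stated statistic", {
    ## genes chosen so every cell has the same library size (44), so
    ## normalization cannot reorder them: log-sd is hi > bal > lo >
    ## const
    n <- 100
    m <- cbind(hi = rep(c(0, 20), n / 2),
               lo = rep(c(11, 9), n / 2),
               const = rep(10, n),
               bal = rep(c(23, 5), n / 2))
    expect_equal(baselineSelect("std", m, 1), "hi")
    expect_equal(baselineSelect("std", m, 4)[4], "const")
    r1 <- baselineSelect("random", m, 2, seed = 4)
    expect_identical(r1, baselineSelect("random", m, 2, seed = 4))
    set.seed(15)
    big <- matrix(rpois(200 * 50, 5), 200, 50)
    expect_length(baselineSelect("dispersion", big, 10), 10)
})

test_that("Leiden resolution matching recovers planted blocks", {
    set.seed(31)
    fix <- blockCounts(nPerPop = 40, pops = 3)
    g <- buildNeighborGraph(fix$counts, fsParam(k = 10, nPCs = 5))
    memb <- clusterToK(g, 3, seed = 1)
    expect_equal(attr(memb, "nCommunities"), 3)
    expect_gt(nmi(fix$labels, memb), 0.95)
})
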