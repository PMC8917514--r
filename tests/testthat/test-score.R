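test_that("observed distribution matches hand enumeration", {
    ## 3 cells, k = 1, neighbor map 1->3, 2->1, 3->1 (1-based)
    g <- new("NeighborGraph", index = cbind(c(3L, 1L, 1L)), k = 1L,
             includesSelf = TRUE)
    p <- observedDistribution(c(1, 0, 2), g)
    ## expressing cells 1 and 3: sums 1+2 = 3 and 2+1 = 3
    expect_equal(pmfSupport(p), 3)
    expect_equal(pmfMass(p), 1)
    ## k = 0 with self: the PMF of the positive counts themselves
    g0 <- new("NeighborGraph", index = matrix(integer(), 3, 0), k = 0L,
              includesSelf = TRUE)
    p0 <- observedDistribution(c(2, 0, 2), g0)
    expect_equal(pmfSupport(p0), 2)
    ## constant counts: point mass at (k+1) * c
    idx <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))
    g2 <- new("NeighborGraph", index = idx, k = 2L, includesSelf = TRUE)
    pc <- observedDistribution(rep(4, 3), g2)
    expect_equal(pmfSupport(pc), 12)
    ## all-zero gene signals the empty-distribution condition
    expect_error(observedDistribution(c(0, 0, 0), g2),
                 class = "knnfs_empty_distribution")
})

test_that("a point-mass gene has identical observed and null distributions", {
    set.seed(30)
    m <- matrix(rpois(40 * 10, 3), 40, 10)
    m[, 1] <- 5  # constant gene
    g <- buildNeighborGraph(m, fsParam(k = 6, nPCs = 4))
    obs <- observedDistribution(m[, 1], g)
    nul <- nullDistribution(m[, 1], 6)
    expect_equal(wassersteinDistance(obs, nul), 0)
})

test_that("score table satisfies its structural invariants", {
    set.seed(40)
    fix <- blockCounts(nPerPop = 25, pops = 3)
    prm <- fsParam(k = 8, nPCs = 5, nWindows = 4, nFeatures = 10)
    tbl <- selectFeatures(fix$counts, prm)
    sc <- tbl$scored
    ## ranks are a permutation of 1..n_scored; unscored genes unranked
    expect_setequal(tbl$rank[sc], seq_len(sum(sc)))
    expect_true(all(is.na(tbl$rank[!sc])))
    ## selected genes form a prefix of the corrected-distance ranking
    expect_setequal(tbl$rank[tbl$selected], seq_len(10))
    ## unscored genes have zero distance and are never selected
    expect_true(all(tbl$rawDistance[!sc] == 0))
    expect_false(any(tbl$selected[!sc]))
    ## population-restricted genes outrank unstructured background
    mkRanks <- tbl$rank[grepl("^MK", tbl$geneId)]
    bgRanks <- tbl$rank[grepl("^BG", tbl$geneId)]
    expect_gt(median(bgRanks, na.rm = TRUE), median(mkRanks, na.rm = TRUE))
    expect_gte(mean(grepl("^MK", selectedGenes(tbl))), 0.8)
})

test_that("window correction subtracts per-window medians exactly", {
    mk <- function(mean, raw) S4Vectors::DataFrame(
        geneId = sprintf("g%02d", seq_along(mean)), meanExpr = mean,
        nPositiveCells = 10L, rawDistance = raw, scored = TRUE,
        window = NA_integer_, correctedDistance = NA_real_,
        rank = NA_integer_, selected = FALSE)
    t1 <- correctDistances(mk(c(1, 2, 3), c(1, 2, 3)), 1)
    expect_equal(t1$correctedDistance, c(-1, 0, 1))
    ## all equal within a window: all zero
    t2 <- correctDistances(mk(1:4, rep(7, 4)), 2)
    expect_equal(t2$correctedDistance, rep(0, 4))
    ## 6 genes, 2 windows of 3 split by expression
    t3 <- correctDistances(mk(c(1, 2, 3, 10, 20, 30),
                              c(5, 1, 3, 10, 2, 6)), 2)
    expect_equal(t3$correctedDistance, c(2, -2, 0, 4, -4, 0))
    expect_equal(t3$window, c(1, 1, 1, 2, 2, 2))
    expect_error(correctDistances(mk(1:3, 1:3), 5), "windows")
})

test_that("every window's median corrected distance is zero", {
    set.seed(50)
    for (w in c(1, 10, 100)) {
        ng <- 500
        tbl <- S4Vectors::DataFrame(
            geneId = sprintf("g%03d", 1:ng),
            meanExpr = rgamma(ng, 2), nPositiveCells = 20L,
            rawDistance = rgamma(ng, 1) * 10, scored = TRUE,
            window = NA_integer_, correctedDistance = NA_real_,
            rank = NA_integer_, selected = FALSE)
        out <- correctDistances(tbl, w)
        meds <- tapply(out$correctedDistance, out$window, median)
        expect_true(all(abs(meds) < 1e-12))
        ## mean mode: every window's mean is zero
        outM <- correctDistances(tbl, w, statistic = "mean")
        mns <- tapply(outM$correctedDistance, outM$window, mean)
        expect_true(all(abs(mns) < 1e-12))
    }
})

test_that("ranked selection honors explicit size, knee and threshold", {
    mk <- function(cd) S4Vectors::DataFrame(
        geneId = sprintf("g%02d", seq_along(cd)), meanExpr = 1,
        nPositiveCells = 10L, rawDistance = abs(cd), scored = TRUE,
        window = 1L, correctedDistance = cd, rank = NA_integer_,
        selected = FALSE)
    ## explicit prefix
    t1 <- rankAndSelect(mk(c(5, 4, 3, 2, 1)), fsParam(nFeatures = 3))
    expect_equal(sum(t1$selected), 3)
    expect_true(all(t1$selected[1:3]))
    ## knee: brute-force chord oracle picks the cut after rank 2
    cd <- c(10, 9, 1, 0.9, 0.8)
    t2 <- rankAndSelect(mk(cd), fsParam(nFeatures = "auto", minDist = 0))
    expect_equal(sum(t2$selected), 2)
    ## minDist removes genes inside the knee prefix
    t3 <- rankAndSelect(mk(c(10, 0.05, 0.04, 0.03, 0.02)),
                        fsParam(nFeatures = "auto", minDist = 0.1))
    expect_equal(selectedGenes(t3), "g01")
    ## flat curve: knee undefined, falls back to threshold with warning
    expect_warning(
        t4 <- rankAndSelect(mk(rep(2, 5)), fsParam(nFeatures = "auto")),
        "knee")
    expect_equal(sum(t4$selected), 5)
})

test_that("the knee matches a brute-force maximum-distance search", {
    set.seed(60)
    for (i in 1:20) {
        y <- sort(rgamma(50, 1), decreasing = TRUE)
        got <- knnfs:::.kneeIndex(y)
        ## oracle: maximum distance below the chord over all positions
        n <- length(y)
        chord <- y[1] + (seq_len(n) - 1) * (y[n] - y[1]) / (n - 1)
        oracle <- which.max(chord - y)
        if ((chord - y)[oracle] > 0)
            expect_equal(got, oracle)
        else
            expect_true(is.na(got))
    }
})

test_that("the pipeline is deterministic and permutation-invariant", {
    set.seed(70)
    fix <- blockCounts(nPerPop = 20, pops = 3)
    prm <- fsParam(k = 8, nPCs = 5, nWindows = 4, nFeatures = 12)
    t1 <- selectFeatures(fix$counts, prm)
    t2 <- selectFeatures(fix$counts, prm)
    expect_identical(as.data.frame(t1), as.data.frame(t2))
    ## permuting cells leaves the per-gene table unchanged
    perm <- sample(nrow(fix$counts))
    t3 <- selectFeatures(fix$counts[perm, ], prm)
    expect_equal(t3$rawDistance, t1$rawDistance, tolerance = 1e-9)
    expect_identical(selectedGenes(t3), selectedGenes(t1))
    ## permuting genes leaves the selected set unchanged
    gperm <- sample(ncol(fix$counts))
    t4 <- selectFeatures(fix$counts[, gperm], prm)
    expect_setequal(selectedGenes(t4), selectedGenes(t1))
})

test_that("montecarlo null mode approximates the exact pipeline", {
    set.seed(80)
    fix <- blockCounts(nPerPop = 15, pops = 2, background = 10)
    pC <- fsParam(k = 5, nPCs = 4, nWindows = 2, nFeatures = 8)
    pM <- fsParam(k = 5, nPCs = 4, nWindows = 2, nFeatures = 8,
                  nullMode = "montecarlo", nMC = 20000)
    tC <- selectFeatures(fix$counts, pC)
    tM <- selectFeatures(fix$counts, pM)
    sc <- tC$scored
    expect_gt(cor(tC$rawDistance[sc], tM$rawDistance[sc]), 0.99)
})
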