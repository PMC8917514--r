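test_that("knnSmooth averages over the neighborhood", {
    ## 3 cells, each cell's neighbors are the other two
    idx <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))
    g <- new("NeighborGraph", index = idx, k = 2L, includesSelf = FALSE)
    m <- matrix(c(2, 4, 6), 3, 1, dimnames = list(NULL, "g"))
    expect_equal(as.vector(knnSmooth(m, g)), c(5, 4, 3))
    ## constant field is preserved; all-zero stays zero
    cst <- matrix(7, 3, 1, dimnames = list(NULL, "g"))
    expect_equal(as.vector(knnSmooth(cst, g)), rep(7, 3))
    expect_equal(as.vector(knnSmooth(cst * 0, g)), rep(0, 3))
    ## self-inclusive variant divides by k + 1
    expect_equal(as.vector(knnSmooth(m, g, includeSelf = TRUE)),
                 c(4, 4, 4))
})

test_that("rank normalization maps to (0, 1] with average ties", {
    expect_equal(rankNormalize(c(5, 1, 3)), c(1, 1 / 3, 2 / 3))
    n <- 7
    expect_equal(rankNormalize(rep(2, n)), rep((n + 1) / (2 * n), n))
    ## invariant under monotone transforms
    set.seed(2)
    v <- rgamma(50, 2)
    expect_equal(rankNormalize(v), rankNormalize(log1p(v)))
})

test_that("cluster scores take the stated percentile per cluster", {
    cs <- matrix(c(1, 1, 1, 0, 0.5, 1), 6, 1,
                 dimnames = list(NULL, "L"))
    cl <- rep(c("a", "b"), each = 3)
    sm <- scoreClusters(cs, cl, percentile = 70)
    expect_equal(sm["a", "L"], 1)
    ## linear interpolation percentile of (0, 0.5, 1) at 70
    expect_equal(sm["b", "L"], 0.7)
    cst <- matrix(0.1, 10, 1, dimnames = list(NULL, "L"))
    expect_equal(scoreClusters(cst, rep("a", 10))[1, 1], 0.1)
    expect_error(scoreClusters(cs, factor(cl, levels = c("a", "b", "c"))),
                 "empty cluster")
})

test_that("label assignment applies the merge-threshold rule", {
    sm <- rbind(c1 = c(A = 0.9, B = 0.2, C = 0.1),
                c2 = c(A = 0.90, B = 0.87, C = 0.1),
                c3 = c(A = 0.90, B = 0.84, C = 0.1),
                c4 = c(A = 0, B = 0, C = 0))
    plain <- assignLabels(sm, mergeThreshold = 0.05)
    expect_equal(plain$label, c("A", "A", "A", "unassigned"))
    merged <- assignLabels(sm, mergeThreshold = 0.05,
                           allowIntermediate = TRUE)
    expect_equal(merged$label[1], "A")
    expect_equal(merged$label[2], "A+B")  # 0.03 <= 0.05: merged
    expect_equal(merged$label[3], "A")    # 0.06 >  0.05: not merged
})

test_that("population matching recovers planted populations exactly", {
    set.seed(77)
    fix <- blockCounts(nPerPop = 30, pops = 6, markersPerPop = 5,
                       markerRate = 6)
    markers <- split(
        sprintf("MK%d_%02d", rep(1:6, each = 5), 1:5),
        rep(1:6, each = 5))
    names(markers) <- paste0("Type", 1:6)
    res <- matchPopulations(fix$counts, paste0("cl", fix$labels), markers,
                            graph = buildNeighborGraph(
                                fix$counts, fsParam(k = 8, nPCs = 5)))
    got <- res$assignment
    expect_setequal(got$cluster, paste0("cl", 1:6))
    expect_equal(got$label[match(paste0("cl", 1:6), got$cluster)],
                 paste0("Type", 1:6))
    expect_true(all(res$scoreMatrix >= 0 & res$scoreMatrix <= 1))
    ## invariant to label order in the marker list
    res2 <- matchPopulations(fix$counts, paste0("cl", fix$labels),
                             rev(markers),
                             graph = buildNeighborGraph(
                                 fix$counts, fsParam(k = 8, nPCs = 5)))
    expect_equal(
        res2$assignment$label[match(got$cluster, res2$assignment$cluster)],
        got$label)
})

test_that("marker lists round-trip through TSV and JSON", {
    mk <- list(Tcell = c("CD3D", "CD3E"), Bcell = c("CD79A", "MS4A1"))
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("Tcell\tCD3D,CD3E", "Bcell\tCD79A,MS4A1"), tsv)
    expect_equal(readMarkers(tsv), mk)
    js <- tempfile(fileext = ".json")
    jsonlite::write_json(mk, js)
    expect_equal(readMarkers(js), mk)
    ## unresolvable markers are dropped with a warning, empty labels stop
    m <- matrix(rpois(40, 2), 10, 4,
                dimnames = list(NULL, c("CD3D", "CD3E", "CD79A", "MS4A1")))
    g <- buildNeighborGraph(m, fsParam(k = 3, nPCs = 2))
    expect_warning(
        labelScores(m, list(T = c("CD3D", "NOPE")), g), "dropped")
    expect_error(
        suppressWarnings(labelScores(m, list(T = "NOPE"), g)),
        "without resolvable")
})
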