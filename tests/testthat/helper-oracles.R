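## Independent oracles used across the test files. Each deliberately
## uses a different algorithm than the package implementation.

## 1-Wasserstein by greedy mass transport between sorted supports (the
## optimal coupling in 1-D): move mass monotonically, accumulate cost.
oracleWasserstein <- function(sup1, mass1, sup2, mass2) {
    i <- j <- 1L
    cost <- 0
    m1 <- mass1
    m2 <- mass2
    while (i <= length(sup1) && j <= length(sup2)) {
        mv <- min(m1[i], m2[j])
        cost <- cost + mv * abs(sup1[i] - sup2[j])
        m1[i] <- m1[i] - mv
        m2[j] <- m2[j] - mv
        if (m1[i] <= 1e-15) i <- i + 1L
        if (j <= length(sup2) && m2[j] <= 1e-15) j <- j + 1L
    }
    cost
}

## Rand-type indices by exhaustive enumeration of all cell pairs.
oraclePairCounts <- function(t, l) {
    n <- length(t)
    a <- b <- c_ <- d <- 0
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            sameT <- t[i] == t[j]
            sameL <- l[i] == l[j]
            if (sameT && sameL) a <- a + 1
            else if (sameT && !sameL) b <- b + 1
            else if (!sameT && sameL) c_ <- c_ + 1
            else d <- d + 1
        }
    }
    c(a = a, b = b, c = c_, d = d)
}

oracleARI <- function(t, l) {
    pc <- oraclePairCounts(t, l)
    n <- length(t)
    total <- choose(n, 2)
    ri <- (pc["a"] + pc["d"]) / total
    ## expected RI from marginal pair counts
    sameT <- (pc["a"] + pc["b"]) / total
    sameL <- (pc["a"] + pc["c"]) / total
    expA <- sameT * sameL * total
    expD <- (1 - sameT) * (1 - sameL) * total
    expRI <- (expA + expD) / total
    maxRI <- 1
    unname((ri - expRI) / (maxRI - expRI))
}

## NMI from an explicitly built contingency table (log base 2 to check
## base independence of the implementation).
oracleNMI <- function(t, l) {
    tt <- table(t, l)
    n <- sum(tt)
    h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
    ht <- h(rowSums(tt) / n)
    hl <- h(colSums(tt) / n)
    if (ht + hl == 0) return(1)
    mi <- 0
    for (i in seq_len(nrow(tt))) {
        for (j in seq_len(ncol(tt))) {
            if (tt[i, j] > 0) {
                pij <- tt[i, j] / n
                mi <- mi + pij * log2(pij / (rowSums(tt)[i] / n *
                                             colSums(tt)[j] / n))
            }
        }
    }
    unname(2 * mi / (ht + hl))
}

## silhouette by the naive double loop over cells, cosine distance
oracleSilhouette <- function(x, labels) {
    cosd <- function(a, b) {
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na == 0) na <- 1
        if (nb == 0) nb <- 1
        1 - sum(a * b) / (na * nb)
    }
    n <- nrow(x)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(labels == labels[i])
        if (length(own) == 1L) { s[i] <- 0; next }
        a <- mean(vapply(setdiff(own, i), function(j)
            cosd(x[i, ], x[j, ]), numeric(1)))
        bs <- vapply(setdiff(unique(labels), labels[i]), function(g) {
            oth <- which(labels == g)
            mean(vapply(oth, function(j) cosd(x[i, ], x[j, ]),
                        numeric(1)))
        }, numeric(1))
        b <- min(bs)
        s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    mean(s)
}

## random PMF on a small integer support
randomPMF <- function(maxSupport = 8, maxMass = 5) {
    npts <- sample(1:maxMass, 1)
    sup <- sort(sample(0:maxSupport, npts))
    mass <- rgamma(npts, 1)
    discretePMF(sup, mass / sum(mass))
}

## small structured count matrix: `pops` blocks of cells, each with a
## private set of marker genes, plus shared background genes
blockCounts <- function(nPerPop = 30, pops = 3, markersPerPop = 8,
                        background = 20, markerRate = 4, bgRate = 1) {
    n <- nPerPop * pops
    lab <- rep(seq_len(pops), each = nPerPop)
    cols <- list()
    for (p in seq_len(pops)) {
        mk <- matrix(0, n, markersPerPop)
        mk[lab == p, ] <- rpois(nPerPop * markersPerPop, markerRate)
        cols[[p]] <- mk
    }
    bg <- matrix(rpois(n * background, bgRate), n, background)
    m <- do.call(cbind, c(cols, list(bg)))
    colnames(m) <- c(
        sprintf("MK%d_%02d", rep(seq_len(pops), each = markersPerPop),
                seq_len(markersPerPop)),
        sprintf("BG%02d", seq_len(background)))
    rownames(m) <- sprintf("c%03d", seq_len(n))
    list(counts = m, labels = lab)
}
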