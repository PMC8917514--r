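#' Create a discrete probability mass function
#'
#' @param support Numeric vector of support points (strictly increasing
#'   after sorting; duplicates are merged by summing their mass).
#' @param mass Non-negative weights; normalized to sum to 1 when
#'   `normalize = TRUE`, otherwise validated as probabilities.
#' @param normalize Divide `mass` by its sum (default `FALSE`).
#'
#' @return A [DiscretePMF-class] object.
#' @examples
#' discretePMF(c(0, 2), c(0.5, 0.5))
#' @export
discretePMF <- function(support, mass, normalize = FALSE) {
    support <- as.numeric(support)
    mass <- as.numeric(mass)
    if (length(support) != length(mass))
        stop("'support' and 'mass' must have equal length")
    keep <- mass != 0
    if (any(keep)) {
        support <- support[keep]
        mass <- mass[keep]
    }
    o <- order(support)
    support <- support[o]
    mass <- mass[o]
    if (anyDuplicated(support)) {
        mass <- as.numeric(tapply(mass, support, sum))
        support <- sort(unique(support))
    }
    if (normalize) {
        tot <- sum(mass)
        if (tot <= 0) stop("total mass must be positive")
        mass <- mass / tot
    }
    new("DiscretePMF", support = support, mass = mass)
}

#' Empirical PMF of a sample
#'
#' @param values Numeric vector of observations.
#' @return A [DiscretePMF-class] with mass proportional to observation
#'   frequency.
#' @export
empiricalPMF <- function(values) {
    if (length(values) == 0L) stop("cannot build a PMF from no values")
    discretePMF(unique(values), tabulate(match(values, unique(values))),
                normalize = TRUE)
}

#' @rdname discretePMF
#' @param p A `DiscretePMF`.
#' @return `pmfSupport()` and `pmfMass()` extract the slots.
#' @export
pmfSupport <- function(p) p@support

#' @rdname discretePMF
#' @export
pmfMass <- function(p) p@mass

## mass vector on the dense integer grid 0..max(support); requires an
## integer support
.denseMass <- function(p) {
    s <- p@support
    if (any(s != round(s)))
        stop("dense-grid operations require an integer support")
    out <- numeric(max(s) + 1)
    out[s + 1] <- p@mass
    out
}

## direct (exact) linear convolution of two mass vectors
.convDirect <- function(a, b) {
    r <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
        if (a[i] != 0)
            r[i:(i + length(b) - 1L)] <- r[i:(i + length(b) - 1L)] + a[i] * b
    }
    r
}

.fftPad <- function(v, len) c(v, numeric(len - length(v)))

## grid size above which convolutions switch from exact accumulation to
## FFT; results differ only at the level of floating-point round-off
.FFT_SWITCH <- 2048L

#' Convolve two discrete PMFs
#'
#' Returns the distribution of the sum of two independent draws. Both
#' PMFs must live on non-negative integer supports.
#'
#' @param p,q [DiscretePMF-class] objects on integer supports.
#' @return A [DiscretePMF-class].
#' @export
convolvePMF <- function(p, q) {
    a <- .denseMass(p)
    b <- .denseMass(q)
    outLen <- length(a) + length(b) - 1L
    if (outLen <= .FFT_SWITCH) {
        r <- .convDirect(a, b)
    } else {
        L <- stats::nextn(outLen, 2)
        r <- Re(stats::fft(stats::fft(.fftPad(a, L)) *
                           stats::fft(.fftPad(b, L)), inverse = TRUE)) / L
        r <- pmax(r[seq_len(outLen)], 0)
    }
    discretePMF(seq_along(r) - 1, r, normalize = TRUE)
}

#' k-fold self-convolution of a discrete PMF
#'
#' Distribution of the sum of `k` independent draws from `p`. Small
#' supports use exact square-and-multiply convolution; large supports a
#' single FFT power step.
#'
#' @param p A [DiscretePMF-class] on a non-negative integer support.
#' @param k Non-negative integer number of draws; `k = 0` gives a point
#'   mass at 0.
#' @return A [DiscretePMF-class].
#' @export
selfConvolvePMF <- function(p, k) {
    k <- as.integer(k)
    if (k < 0) stop("'k' must be non-negative")
    if (k == 0L) return(discretePMF(0, 1))
    if (k == 1L) return(p)
    m <- .denseMass(p)
    outLen <- (length(m) - 1L) * k + 1L
    if (outLen <= .FFT_SWITCH) {
        ## exact square-and-multiply
        res <- NULL
        base <- m
        kk <- k
        while (kk > 0L) {
            if (kk %% 2L == 1L)
                res <- if (is.null(res)) base else .convDirect(res, base)
            kk <- kk %/% 2L
            if (kk > 0L) base <- .convDirect(base, base)
        }
        r <- res
    } else {
        L <- stats::nextn(outLen, 2)
        r <- Re(stats::fft(stats::fft(.fftPad(m, L))^k, inverse = TRUE)) / L
        r <- pmax(r[seq_len(outLen)], 0)
    }
    discretePMF(seq_along(r) - 1, r, normalize = TRUE)
}

#' 1-Wasserstein distance between two discrete distributions
#'
#' The earth mover's distance on the line: the integral of the absolute
#' difference of the two cumulative distribution functions over the
#' merged support. Symmetric, non-negative, and zero exactly when the
#' distributions coincide.
#'
#' @param p,q [DiscretePMF-class] objects (any non-negative real
#'   support).
#' @return Non-negative numeric scalar.
#' @examples
#' wassersteinDistance(discretePMF(0, 1), discretePMF(5, 1))  # 5
#' @export
wassersteinDistance <- function(p, q) {
    stopifnot(is(p, "DiscretePMF"), is(q, "DiscretePMF"))
    validObject(p)
    validObject(q)
    s <- sort(unique(c(p@support, q@support)))
    if (length(s) == 1L) return(0)
    Fp <- cumsum(.massOn(p, s))
    Fq <- cumsum(.massOn(q, s))
    n <- length(s)
    sum(abs(Fp[-n] - Fq[-n]) * diff(s))
}

## mass of p re-expressed on an encompassing grid s
.massOn <- function(p, s) {
    out <- numeric(length(s))
    out[match(p@support, s)] <- p@mass
    out
}

#' Total-variation distance between two discrete PMFs
#'
#' Half the L1 distance between mass functions on the merged support.
#' Used to compare the exact convolution null with its Monte-Carlo
#' estimate.
#'
#' @inheritParams wassersteinDistance
#' @return Numeric in `[0, 1]`.
#' @export
tvDistance <- function(p, q) {
    s <- sort(unique(c(p@support, q@support)))
    sum(abs(.massOn(p, s) - .massOn(q, s))) / 2
}
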