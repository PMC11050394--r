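# Dinucleotide background p1(n) = f(prev) f(cur) in row order
# n = let(prev) + 4 (let(cur) - 1).
.dinucBackground <- function(baseFreq) {
    as.vector(outer(baseFreq, baseFreq))
}

#' Dinucleotide row index
#'
#' Row of the 16-row weight matrix addressed by the ordered pair
#' (previous base, current base): n = let(prev) + 4 (let(cur) - 1) with
#' let(a)=1, let(t)=2, let(c)=3, let(g)=4.
#'
#' @param prev,cur single bases ("a", "t", "c", "g").
#' @return integer row index in 1..16.
#' @export
dinucleotideRow <- function(prev, cur) {
    p <- match(tolower(prev), .BASES)
    q <- match(tolower(cur), .BASES)
    if (anyNA(p) || anyNA(q)) stop("bases must be one of a, t, c, g")
    as.integer(p + 4L * (q - 1L))
}

#' Random start matrix
#'
#' A raw 16 x L matrix of i.i.d. uniform weights on [-10, 10]; the seed of
#' every start matrix is recorded by the caller for reproducibility.
#'
#' @param L number of columns.
#' @param seed optional seed.
#' @return 16 x L numeric matrix.
#' @export
randomPWM <- function(L, seed = NULL) {
    m <- .withSeed(seed, matrix(runif(16L * L, -10, 10), nrow = 16L))
    rownames(m) <- .DINUC
    m
}

#' Constrain a weight matrix
#'
#' Maps a raw matrix to the constrained scoring matrix by the affine
#' transform m' = alpha (m - Kbar) + K0, where Kbar is the p1 x p2
#' weighted mean of m (p2 uniform over columns) and alpha the positive
#' root of the induced quadratic.  The transformed matrix has weighted
#' mean exactly K0 and fluctuation norm R0^2, i.e. per-cell weighted
#' variance R0^2 / (16 L).  With the defaults K0 = -1 and R0^2 =
#' 300 sqrt(L) the expected score of a random aligned base is about -1.14
#' per-cell standard deviations, the negative-drift regime in which local
#' alignment stays localized; a matrix already satisfying both
#' constraints is a fixed point, and the transform is idempotent.
#'
#' @param m 16 x L numeric matrix or a \code{RepeatPWM}.
#' @param p1 dinucleotide background probabilities (16 values summing
#'   to 1), e.g. from the scanned genome's base frequencies.
#' @param R0sq target fluctuation norm (16 L times the per-cell weighted
#'   variance).
#' @param K0 target weighted mean.
#' @return a \code{RepeatPWM} with the constraints satisfied.
#' @export
transformPWM <- function(m, p1, R0sq, K0 = -1) {
    if (is(m, "RepeatPWM")) {
        if (missing(p1)) p1 <- m@p1
        if (missing(R0sq)) R0sq <- m@R0sq
        m <- m@weights
    }
    stopifnot(is.matrix(m), nrow(m) == 16L)
    stopifnot(length(p1) == 16L, abs(sum(p1) - 1) < 1e-9)
    stopifnot(R0sq > 0)
    L <- ncol(m)
    wts <- outer(p1, rep(1 / L, L))
    Kbar <- sum(m * wts)
    varw <- sum(m^2 * wts) - Kbar^2
    if (varw <= .Machine$double.eps * max(1, sum(m^2)))
        stop("degenerate matrix: zero weighted variance")
    targetVar <- R0sq / L - K0^2
    if (targetVar <= 0)
        stop("R0sq too small: R0sq / L must exceed K0^2")
    alpha <- sqrt(targetVar / varw)
    w <- alpha * (m - Kbar) + K0
    rownames(w) <- .DINUC
    new("RepeatPWM", weights = w, p1 = as.numeric(p1), R0sq = R0sq,
        K0 = K0, transformed = TRUE)
}

#' RepeatPWM accessors
#' @param pwm a \code{RepeatPWM}.
#' @return \code{pwmWeights}: the 16 x L matrix; \code{pwmBackground}: p1;
#'   \code{pwmLength}: number of columns; \code{pwmNormSq}: weighted second
#'   moment; \code{pwmWeightedMean}: weighted mean.
#' @export
pwmWeights <- function(pwm) pwm@weights

#' @rdname pwmWeights
#' @export
pwmBackground <- function(pwm) pwm@p1

#' @rdname pwmWeights
#' @export
pwmLength <- function(pwm) ncol(pwm@weights)

#' @rdname pwmWeights
#' @export
pwmNormSq <- function(pwm) {
    # weighted norm: L times the per-cell weighted second moment
    L <- pwmLength(pwm)
    wts <- outer(pwm@p1, rep(1 / L, L))
    L * sum(pwm@weights^2 * wts)
}

#' @rdname pwmWeights
#' @export
pwmWeightedMean <- function(pwm) {
    L <- pwmLength(pwm)
    sum(pwm@weights * outer(pwm@p1, rep(1 / L, L)))
}

# Row permutation sending dinucleotide (k,l) to (comp(l), comp(k)).
# With codes a=0,t=1,c=2,g=3 the complement is code XOR 1 (a<->t, c<->g);
# row n-1 = prev + 4*cur.
.invertRowPerm <- local({
    prev <- rep(0:3, times = 4)
    cur <- rep(0:3, each = 4)
    nprev <- bitwXor(cur, 1L)
    ncur <- bitwXor(prev, 1L)
    nprev + 4L * ncur + 1L
})

#' Reverse-complement a PWM
#'
#' Rotates the matrix 180 degrees along the columns and exchanges rows
#' between complementary dinucleotides, so that scanning the forward
#' strand with the inverted matrix finds reverse-strand copies.  The
#' background p1 is remapped consistently.  The operation is an involution.
#'
#' @param pwm a \code{RepeatPWM}.
#' @return the inverted \code{RepeatPWM}.
#' @export
invertPWM <- function(pwm) {
    w <- pwm@weights
    wi <- w[, rev(seq_len(ncol(w))), drop = FALSE]
    wi2 <- wi
    wi2[.invertRowPerm, ] <- wi
    p1 <- pwm@p1
    p1i <- p1
    p1i[.invertRowPerm] <- p1
    rownames(wi2) <- .DINUC
    new("RepeatPWM", weights = wi2, p1 = p1i, R0sq = pwm@R0sq,
        K0 = pwm@K0, transformed = pwm@transformed)
}

#' Accumulate the dinucleotide frequency matrix from alignment traces
#'
#' For every trace position i >= 2 aligning a base to a matrix column,
#' the cell (n, column) is incremented, where n is the dinucleotide row of
#' (previous trace base, current base).  Positions whose own column or
#' whose neighbouring base entry is a deletion contribute nothing, as does
#' the first trace position (it has no left context) and any position
#' involving an ambiguous base.
#'
#' @param traces list of alignment traces as returned by
#'   \code{\link{alignProfile}} (components \code{s1}: base codes with NA
#'   at deletions, \code{s2}: 1-based column indices with NA at deletions).
#' @param L number of matrix columns.
#' @return 16 x L integer count matrix.
#' @export
accumulateMAT <- function(traces, L) {
    MAT <- matrix(0L, nrow = 16L, ncol = L, dimnames = list(.DINUC, NULL))
    for (tr in traces) {
        s1 <- tr$s1
        s2 <- tr$s2
        k <- length(s1)
        if (k < 2L) next
        i <- 2:k
        ok <- !is.na(s1[i - 1L]) & !is.na(s1[i]) & !is.na(s2[i]) &
            s1[i - 1L] < 4L & s1[i] < 4L
        if (!any(ok)) next
        cols <- s2[i][ok]
        if (any(cols < 1L | cols > L)) stop("trace column outside 1..L")
        n <- s1[i - 1L][ok] + 4L * s1[i][ok] + 1L
        for (q in seq_along(n)) MAT[n[q], cols[q]] <- MAT[n[q], cols[q]] + 1L
    }
    MAT
}

#' Standardize a count matrix against its margin-product expectation
#'
#' Compares the counts with the expectation N p(i,j), p(i,j) =
#' x(i) y(j) / N^2 from the row and column margins.  On the
#' \code{"ratio"} scale (used to rebuild the scoring matrix from the
#' dinucleotide frequency matrix), M(i,j) = (V - N p) / (N p (1 - p)),
#' essentially the observed/expected rate ratio minus one: bounded,
#' independent of the total count, so a strongly covered cell cannot
#' dominate the refined matrix.  On the \code{"deviate"} scale the
#' denominator is under a square root and the entries are approximately
#' standard normal under independent margins (the form used for the
#' enrichment statistics).  Cells with degenerate p (0 or 1) are set
#' to 0.
#'
#' @param V non-negative count matrix (any dimensions).
#' @param scale "ratio" (default) or "deviate".
#' @return numeric matrix of standardized deviations.
#' @export
standardizeCounts <- function(V, scale = c("ratio", "deviate")) {
    scale <- match.arg(scale)
    N <- sum(V)
    if (N == 0) stop("empty count matrix")
    p <- outer(rowSums(V), colSums(V)) / N^2
    M <- matrix(0, nrow(V), ncol(V), dimnames = dimnames(V))
    ok <- p > 0 & p < 1
    denom <- N * p[ok] * (1 - p[ok])
    if (scale == "deviate") denom <- sqrt(denom)
    M[ok] <- (V[ok] - N * p[ok]) / denom
    M
}

#' Save / load a PWM as plain text
#'
#' The file holds a one-line JSON header (L, R0sq, K0, p1) followed by the
#' 16 x L weight matrix, one row per line.
#'
#' @param pwm a \code{RepeatPWM}.
#' @param path file path.
#' @return \code{readPWM} returns the \code{RepeatPWM}.
#' @export
writePWM <- function(pwm, path) {
    hdr <- jsonlite::toJSON(list(L = pwmLength(pwm), R0sq = pwm@R0sq,
                                 K0 = pwm@K0, p1 = pwm@p1,
                                 transformed = pwm@transformed),
                            auto_unbox = TRUE, digits = NA)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(hdr), con)
    utils::write.table(pwm@weights, con, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' @rdname writePWM
#' @export
readPWM <- function(path) {
    lines <- readLines(path)
    hdr <- jsonlite::fromJSON(lines[1L])
    w <- as.matrix(read.table(text = lines[-1L]))
    dimnames(w) <- list(.DINUC, NULL)
    new("RepeatPWM", weights = w, p1 = as.numeric(hdr$p1),
        R0sq = hdr$R0sq, K0 = hdr$K0, transformed = isTRUE(hdr$transformed))
}
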