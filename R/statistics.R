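#' Per-family base count matrix from re-aligned members
#'
#' Re-aligns every member hit window to the family matrix and counts, for
#' each matrix column, the bases aligned to it: M4(b, j) is incremented
#' for every aligned pair with neither side deleted.  Reverse-strand
#' members are re-aligned as the reverse complement of their window.
#'
#' @param family a \code{RepeatFamily}, or a \code{GRanges} of hits (then
#'   \code{pwm} must be given).
#' @param genome the \code{GenomeIndex} the hits refer to.
#' @param config an \code{\link{ipConfig}}.
#' @param pwm matrix to re-align against (defaults to the family's).
#' @return list with \code{M4} (4 x L count matrix, rows a/t/c/g),
#'   \code{nAligned}, \code{nSkipped} (members with score 0), and the
#'   member traces.
#' @export
buildCountMatrix <- function(family, genome, config, pwm = NULL) {
    if (is(family, "RepeatFamily")) {
        hits <- family@hits
        if (is.null(pwm)) pwm <- family@pwm
    } else hits <- family
    stopifnot(!is.null(pwm))
    L <- pwmLength(pwm)
    M4 <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(.BASES, NULL))
    nskip <- 0L
    traces <- vector("list", length(hits))
    LS <- genomeLength(genome)
    for (k in seq_along(hits)) {
        ws <- mcols(hits)$wstart[k]
        if (is.null(ws) || is.na(ws))
            ws <- recordToConcat(genome, as.character(seqnames(hits))[k],
                                 start(hits)[k])
        ws <- min(max(1L, ws), LS - config$window + 1L)
        codes <- genome@seq[ws:(ws + config$window - 1L)]
        if (as.character(strand(hits))[k] == "-")
            codes <- rev(ifelse(codes < 4L, bitwXor(codes, 1L), 4L))
        tr <- .cpp_align_fit(codes, pwm@weights, config$gapPenalty,
                             identical(config$scanMode, "anchored"))
        traces[[k]] <- tr
        if (tr$score <= 0 || !length(tr$s1)) {
            nskip <- nskip + 1L
            next
        }
        ok <- !is.na(tr$s1) & !is.na(tr$s2) & tr$s1 < 4L
        b <- tr$s1[ok] + 1L
        j <- tr$s2[ok]
        for (q in seq_along(b)) M4[b[q], j[q]] <- M4[b[q], j[q]] + 1L
    }
    if (nskip > 0L)
        warning(nskip, " member(s) failed to re-align and were skipped")
    list(M4 = M4, nAligned = length(hits) - nskip, nSkipped = nskip,
         traces = traces)
}

#' Per-column standardized base deviations
#'
#' w(i,j) = (M4(i,j) - N_j p(i)) / sqrt(N_j p(i) (1 - p(i))), where N_j is
#' the number of bases aligned to column j and p(i) the base probabilities
#' over all members of the family (row sums of M4 normalized).  Rows with
#' degenerate p (0 or 1) get w = 0; columns with N_j = 0 get w = 0.
#'
#' @param M4 4 x L count matrix.
#' @param p optional base probabilities (default family-wide, from M4).
#' @return 4 x L numeric matrix w.
#' @export
columnDeviation <- function(M4, p = NULL) {
    if (is.null(p)) {
        y <- rowSums(M4)
        if (sum(y) == 0) stop("empty count matrix")
        p <- y / sum(y)
    }
    Nj <- colSums(M4)
    w <- matrix(0, nrow(M4), ncol(M4), dimnames = dimnames(M4))
    ok_row <- p > 0 & p < 1
    ok_col <- Nj > 0
    for (i in which(ok_row)) {
        denom <- sqrt(Nj[ok_col] * p[i] * (1 - p[i]))
        w[i, ok_col] <- (M4[i, ok_col] - Nj[ok_col] * p[i]) / denom
    }
    w
}

#' Normalized per-column conservation statistic
#'
#' X(j) = sqrt(2 chi(j)) - sqrt(2 n - 1) with chi(j) the sum of squared
#' standardized base deviations of column j and n = 3 degrees of freedom;
#' approximately standard normal under the multinomial null, large where a
#' column's base distribution departs from the family background.
#'
#' @param w either the 4 x L deviation matrix (a full vector of X is
#'   returned) or a single column's deviations; alternatively chi values
#'   via \code{chi}.
#' @param n degrees of freedom (3 for the 4-letter alphabet).
#' @param chi optional precomputed chi value(s).
#' @return numeric X value(s).
#' @export
columnStatistic <- function(w = NULL, n = 3, chi = NULL) {
    if (is.null(chi)) {
        chi <- if (is.matrix(w)) colSums(w^2) else sum(w^2)
    }
    sqrt(2 * chi) - sqrt(2 * n - 1)
}

#' Strict-majority symbolic consensus
#'
#' Per column, the base present in strictly more than half of the aligned
#' members, otherwise "-"; empty columns give "-".
#'
#' @param M4 4 x L count matrix.
#' @return consensus string of length L over a, t, c, g, -.
#' @export
symbolicConsensus <- function(M4) {
    Nj <- colSums(M4)
    out <- rep("-", ncol(M4))
    for (j in which(Nj > 0)) {
        i <- which.max(M4[, j])
        if (M4[i, j] > Nj[j] / 2) out[j] <- .BASES[i]
    }
    paste(out, collapse = "")
}

#' Full consensus profile of a family
#'
#' Combines the count matrix, the standardized deviations of every column
#' (against the family-wide base background), the chi and X conservation
#' statistics and the strict-majority symbolic consensus.
#'
#' @param M4 4 x L count matrix (from \code{\link{buildCountMatrix}}).
#' @return list of class \code{ConsensusProfile}: \code{M4}, \code{Nj},
#'   \code{p}, \code{w}, \code{chi}, \code{X}, \code{consensus}.
#' @export
consensusProfile <- function(M4) {
    y <- rowSums(M4)
    p <- if (sum(y) > 0) y / sum(y) else rep(0.25, 4)
    w <- columnDeviation(M4, p)
    chi <- colSums(w^2)
    out <- list(M4 = M4, Nj = colSums(M4), p = p, w = w, chi = chi,
                X = columnStatistic(chi = chi),
                consensus = symbolicConsensus(M4))
    class(out) <- "ConsensusProfile"
    out
}

#' @export
print.ConsensusProfile <- function(x, ...) {
    cat("ConsensusProfile over", ncol(x$M4), "columns;",
        sum(x$Nj > 0), "columns populated\n")
    cat("  X(j): max", sprintf("%.2f", max(x$X[x$Nj > 0])),
        " conserved columns (X > 3):", sum(x$X > 3 & x$Nj > 0), "\n")
    cat("  consensus:", substr(x$consensus, 1, 60),
        if (nchar(x$consensus) > 60) "..." else "", "\n")
    invisible(x)
}

#' Write the numeric + symbolic consensus report
#'
#' @param profile a \code{ConsensusProfile}.
#' @param path output file; a plain-text table of M4, w, chi and X per
#'   column preceded by the symbolic consensus.
#' @export
writeConsensusReport <- function(profile, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# consensus ", profile$consensus),
                 paste("j", paste0("n_", .BASES, collapse = "\t"),
                       paste0("w_", .BASES, collapse = "\t"),
                       "chi", "X", sep = "\t")), con)
    for (j in seq_len(ncol(profile$M4)))
        writeLines(paste(j, paste(profile$M4[, j], collapse = "\t"),
                         paste(sprintf("%.4f", profile$w[, j]),
                               collapse = "\t"),
                         sprintf("%.4f", profile$chi[j]),
                         sprintf("%.4f", profile$X[j]), sep = "\t"), con)
    invisible(path)
}

#' Export aligned members for logo rendering
#'
#' Writes one sequence per member: the member's bases at matrix columns
#' 1..L, with bases opposite a column deletion removed, so any sequence
#' logo renderer can display the family alignment.
#'
#' @param counts result of \code{\link{buildCountMatrix}} (uses its
#'   traces).
#' @param L number of matrix columns.
#' @param path output multi-FASTA path.
#' @export
writeAlignedMembers <- function(counts, L, path) {
    con <- file(path, "w")
    on.exit(close(con))
    k <- 0L
    for (tr in counts$traces) {
        if (is.null(tr) || !length(tr$s1) || tr$score <= 0) next
        k <- k + 1L
        cols <- rep("-", L)
        ok <- !is.na(tr$s1) & !is.na(tr$s2)
        cols[tr$s2[ok]] <- c(.BASES, "n")[tr$s1[ok] + 1L]
        writeLines(c(paste0(">member_", k),
                     toupper(paste(cols, collapse = ""))), con)
    }
    invisible(path)
}

#' Intersect repeat hits with annotated features
#'
#' In \code{mode = "gene"} a pair is reported when the overlap exceeds
#' half the repeat length or half the feature length; in \code{mode =
#' "repeat"} (annotated-repeat mode) only the repeat-length rule applies.
#' Both rules are strict (> 50\%), and many-to-many pairs are allowed.
#'
#' @param hits repeat \code{GRanges}.
#' @param features annotation \code{GRanges}.
#' @param mode "gene" or "repeat".
#' @param minFraction overlap fraction threshold (default 0.5).
#' @return data.frame with one row per intersecting pair: hit and feature
#'   indices, overlap width, plus \code{family} and \code{class} columns
#'   when present in the inputs.
#' @export
intersectFeatures <- function(hits, features, mode = c("gene", "repeat"),
                              minFraction = 0.5) {
    mode <- match.arg(mode)
    ov <- findOverlaps(hits, features, ignore.strand = TRUE)
    if (!length(ov))
        return(data.frame(hit = integer(0), feature = integer(0),
                          overlap = integer(0)))
    q <- queryHits(ov); s <- subjectHits(ov)
    w <- width(pintersect(ranges(hits)[q], ranges(features)[s]))
    keep <- w > minFraction * width(hits)[q]
    if (mode == "gene")
        keep <- keep | (w > minFraction * width(features)[s])
    out <- data.frame(hit = q[keep], feature = s[keep],
                      overlap = w[keep])
    if (!is.null(mcols(hits)$family))
        out$family <- mcols(hits)$family[out$hit]
    if (!is.null(mcols(features)$class))
        out$class <- mcols(features)$class[out$feature]
    out
}

#' Class-by-family enrichment matrix
#'
#' Counts intersections between annotation classes (rows) and repeat
#' families (columns) and standardizes the count matrix against the
#' margin-product expectation, v'(i,j) = (v - n p) / sqrt(n p (1 - p))
#' with p(i,j) = x(i) y(j) / n^2; approximately standard normal under
#' independence, large values flag families enriched in a class.
#'
#' @param pairs data.frame with columns \code{class} and \code{family}
#'   (one row per intersection), or a prebuilt count matrix.
#' @return list with \code{V} (counts) and \code{Vprime} (standardized),
#'   plus a \code{flagged} logical matrix (|v'| > 3).
#' @export
classFamilyEnrichment <- function(pairs) {
    V <- if (is.matrix(pairs) || is.table(pairs)) unclass(pairs)
        else unclass(table(pairs$class, pairs$family))
    if (sum(V) == 0)
        return(list(V = V, Vprime = V * 0, flagged = V > Inf))
    Vp <- standardizeCounts(V, scale = "deviate")
    list(V = V, Vprime = Vp, flagged = abs(Vp) > 3)
}

#' Length distribution of repeat hits
#'
#' @param hits \code{GRanges} (or numeric lengths).
#' @param breaks passed to \code{hist}.
#' @return list with the histogram counts table and min/max/mean lengths;
#'   empty inputs give an empty table.
#' @export
lengthHistogram <- function(hits, breaks = 30) {
    len <- if (is.numeric(hits)) hits else width(hits)
    if (!length(len))
        return(list(table = data.frame(mid = numeric(0),
                                       count = integer(0)),
                    min = NA, max = NA, mean = NA))
    h <- graphics::hist(len, breaks = breaks, plot = FALSE)
    list(table = data.frame(mid = h$mids, count = h$counts),
         min = min(len), max = max(len), mean = mean(len))
}
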