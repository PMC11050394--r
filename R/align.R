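#' Dinucleotide match score
#'
#' Weight of aligning \code{base} to matrix column \code{column} given the
#' preceding window base.  When the predecessor is unavailable (first
#' window position) or either base is ambiguous, the neutral score 0 is
#' returned; an N base never earns a match bonus.
#'
#' @param prevBase previous window base or NA.
#' @param base current base.
#' @param column matrix column (1..L).
#' @param pwm a \code{RepeatPWM}.
#' @return numeric score.
#' @export
matchScore <- function(prevBase, base, column, pwm) {
    stopifnot(column >= 1L, column <= pwmLength(pwm))
    if (is.na(prevBase) || is.na(base)) return(0)
    p <- match(tolower(prevBase), .BASES)
    q <- match(tolower(base), .BASES)
    if (is.na(p) || is.na(q)) return(0)
    pwm@weights[p + 4L * (q - 1L), column]
}

# Normalize a window argument to integer base codes.
.asCodes <- function(window) {
    if (is.character(window) || is(window, "XString")) .encodeDNA(as.character(window))
    else as.integer(window)
}

#' Local profile-sequence alignment
#'
#' Smith-Waterman style local dynamic programming between the matrix
#' columns and a DNA window.  A diagonal move aligning window base i to
#' column j scores the weight of the (base i-1, base i) dinucleotide at
#' column j (neutral at the first window position and at N bases); gaps on
#' either side cost \code{gapPenalty} per symbol.  The empty alignment with
#' score 0 is allowed.  Backtracking ties prefer diagonal, then the
#' base-consuming gap, then the column-consuming gap, so traces are
#' deterministic.
#'
#' @param pwm a \code{RepeatPWM}.
#' @param window base codes, a character string, or a \code{DNAString}.
#' @param gapPenalty linear gap penalty (> 0).
#' @param trace if FALSE only the score is computed (faster path).
#' @param mode \code{"local"} (Smith-Waterman style, defines the classic
#'   F_max), \code{"fit"} (every matrix column consumed, window bases
#'   outside the aligned region free on both sides), or \code{"anchored"}
#'   (fit with the leading window bases paid, so the alignment is pinned
#'   to the window start).  Fit/anchored traces keep family members in a
#'   common column register and are used when re-estimating the frequency
#'   matrix.
#' @return a list of class \code{alignmentTrace}: \code{score} (F_max),
#'   \code{s1} base codes with NA at deletions, \code{s2} column indices
#'   with NA where a base is aligned to no column, \code{first}/\code{last}
#'   1-based window positions of the aligned span.
#' @export
alignProfile <- function(pwm, window, gapPenalty, trace = TRUE,
                         mode = c("local", "fit", "anchored")) {
    mode <- match.arg(mode)
    codes <- .asCodes(window)
    stopifnot(gapPenalty > 0)
    if (length(codes) < 2L) {
        res <- list(score = 0, s1 = integer(0), s2 = integer(0),
                    first = NA_integer_, last = NA_integer_)
        class(res) <- "alignmentTrace"
        return(res)
    }
    if (mode %in% c("fit", "anchored")) {
        res <- .cpp_align_fit(codes, pwm@weights, gapPenalty,
                              mode == "anchored")
    } else if (trace) {
        res <- .cpp_align_trace(codes, pwm@weights, gapPenalty)
    } else {
        res <- list(score = .cpp_align_score(codes, pwm@weights, gapPenalty),
                    s1 = NULL, s2 = NULL, first = NA_integer_,
                    last = NA_integer_)
    }
    class(res) <- "alignmentTrace"
    res
}

#' @export
print.alignmentTrace <- function(x, ...) {
    cat("alignmentTrace: score", format(x$score, digits = 6))
    if (!is.null(x$s1))
        cat(",", length(x$s1), "aligned positions, window span",
            x$first, "-", x$last)
    cat("\n")
    invisible(x)
}
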