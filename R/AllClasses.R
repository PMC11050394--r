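#' @import methods
NULL

# Base coding used throughout the package: a=0, t=1, c=2, g=3, N=4.
# This is the let() order of the dinucleotide row index
# n = let(prev) + 4 * (let(cur) - 1), let(a)=1, let(t)=2, let(c)=3, let(g)=4.
.BASES <- c("a", "t", "c", "g")
.DINUC <- as.vector(outer(.BASES, .BASES, paste0))   # n = prev + 4*(cur-1)

#' GenomeIndex: a genome as one concatenated coded sequence
#'
#' Holds the analyzed genome in the form the scanner works on: every record
#' concatenated into a single sequence over \{a,t,c,g,N\}, a per-record
#' coordinate map, the genome-wide base frequencies over non-N positions,
#' and a per-base mask channel recording bases already claimed by an
#' accepted repeat family.
#'
#' @slot seq integer vector of base codes (a=0, t=1, c=2, g=3, N=4).
#' @slot records data.frame with columns \code{name}, \code{length},
#'   \code{offset}; offsets are 0-based starts in the concatenation.
#' @slot baseFreq named numeric of length 4 (a, t, c, g) over non-N bases.
#' @slot mask logical vector, same length as \code{seq}.
#' @exportClass GenomeIndex
setClass("GenomeIndex",
    representation(seq = "integer", records = "data.frame",
                   baseFreq = "numeric", mask = "logical"))

setValidity("GenomeIndex", function(object) {
    msg <- character()
    L <- length(object@seq)
    if (sum(object@records$length) != L)
        msg <- c(msg, "record lengths do not sum to concatenated length")
    if (is.unsorted(object@records$offset, strictly = TRUE) &&
        nrow(object@records) > 1)
        msg <- c(msg, "offsets must be strictly increasing")
    if (anyDuplicated(object@records$name))
        msg <- c(msg, "duplicate record names")
    if (abs(sum(object@baseFreq) - 1) > 1e-12 && any(object@seq < 4L))
        msg <- c(msg, "base frequencies must sum to 1")
    if (length(object@mask) != L)
        msg <- c(msg, "mask length must equal sequence length")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeIndex", function(object) {
    cat("GenomeIndex with", nrow(object@records), "record(s),",
        length(object@seq), "bp\n")
    cat("  base frequencies:",
        paste(sprintf("%s=%.3f", names(object@baseFreq), object@baseFreq),
              collapse = " "), "\n")
    nm <- sum(object@mask)
    if (nm > 0) cat("  masked:", nm, "bp\n")
})

#' RepeatPWM: dinucleotide position weight matrix
#'
#' A 16-row (ordered dinucleotide) by L-column weight matrix together with
#' the dinucleotide background probabilities p1(n) = f(k) f(l) it was
#' constrained against.  After \code{\link{transformPWM}} the matrix
#' satisfies the two normalization constraints: its p1 x p2 weighted mean
#' equals K0 and its weighted second moment equals R0^2 (p2 uniform over
#' columns).
#'
#' @slot weights 16 x L numeric matrix, rows in dinucleotide order
#'   (n = let(prev) + 4 (let(cur) - 1)).
#' @slot p1 numeric(16) dinucleotide background probabilities.
#' @slot R0sq target weighted second moment.
#' @slot K0 target weighted mean.
#' @slot transformed logical, whether the constraints currently hold.
#' @exportClass RepeatPWM
setClass("RepeatPWM",
    representation(weights = "matrix", p1 = "numeric", R0sq = "numeric",
                   K0 = "numeric", transformed = "logical"))

setValidity("RepeatPWM", function(object) {
    msg <- character()
    if (nrow(object@weights) != 16L)
        msg <- c(msg, "weight matrix must have 16 rows")
    if (length(object@p1) != 16L)
        msg <- c(msg, "p1 must have 16 entries")
    if (abs(sum(object@p1) - 1) > 1e-9)
        msg <- c(msg, "p1 must sum to 1")
    if (object@transformed) {
        L <- ncol(object@weights)
        wts <- outer(object@p1, rep(1 / L, L))
        Kbar <- sum(object@weights * wts)
        if (abs(L * sum(object@weights^2 * wts) - object@R0sq) >
            1e-6 * object@R0sq)
            msg <- c(msg, "weighted norm constraint violated")
        if (abs(Kbar - object@K0) > 1e-7)
            msg <- c(msg, "weighted mean constraint violated")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "RepeatPWM", function(object) {
    cat("RepeatPWM: 16 x", ncol(object@weights), "dinucleotide weight matrix\n")
    cat(sprintf("  weighted mean %.4f, fluctuation norm %.2f (target K0=%g, R0^2=%.2f)\n",
                pwmWeightedMean(object), pwmNormSq(object),
                object@K0, object@R0sq))
    cat("  transformed:", object@transformed, "\n")
})

#' RepeatFamily: an accepted dispersed-repeat family
#'
#' @slot id integer family identifier.
#' @slot pwm the accepted \code{RepeatPWM} (Mt_max).
#' @slot Nmax number of members at acceptance.
#' @slot iMax refinement iteration at which the family was accepted.
#' @slot hits \code{GRanges} of member hits (discovery coordinates, with
#'   metadata columns \code{Z} and \code{wstart}).
#' @slot Z0 per-family significance threshold after FDR calibration
#'   (\code{NA} until calibrated).
#' @slot fdr data.frame FDR table over the threshold grid, or NULL-like
#'   empty data.frame before calibration.
#' @exportClass RepeatFamily
setClass("RepeatFamily",
    representation(id = "integer", pwm = "RepeatPWM", Nmax = "integer",
                   iMax = "integer", hits = "ANY", Z0 = "numeric",
                   fdr = "data.frame"))

setMethod("show", "RepeatFamily", function(object) {
    cat("RepeatFamily", object@id, "with", object@Nmax,
        "members (accepted at iteration", paste0(object@iMax, ")"), "\n")
    if (!is.na(object@Z0))
        cat("  calibrated Z0 =", object@Z0, "\n")
})

#' PlantedGenome: synthetic genome with planted repeat families
#'
#' @slot genome a \code{GenomeIndex}.
#' @slot truth \code{GRanges} of planted copies with metadata columns
#'   \code{family}, \code{nSub}, \code{nIndel}.
#' @slot mothers character vector of mother sequences.
#' @slot params list of generator parameters (including the seed).
#' @exportClass PlantedGenome
setClass("PlantedGenome",
    representation(genome = "GenomeIndex", truth = "ANY",
                   mothers = "character", params = "list"))

setMethod("show", "PlantedGenome", function(object) {
    cat("PlantedGenome:", length(object@genome@seq), "bp,",
        length(object@truth), "planted copies of",
        length(object@mothers), "mother sequence(s)\n")
    cat("  divergence x =", object@params$x, "\n")
})

#' Accessors for planted genomes
#' @param x a \code{PlantedGenome}.
#' @return \code{plantedTruth} returns the truth \code{GRanges}.
#' @export
plantedTruth <- function(x) {
    stopifnot(is(x, "PlantedGenome"))
    x@truth
}
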