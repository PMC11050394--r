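#' Search a genome with an accepted family matrix on both strands
#'
#' Scans the forward sequence with the family matrix (direct hits, strand
#' "+") and with its reverse complement (inverted hits, reported on strand
#' "-"); coordinates always refer to the forward reference.  When a
#' shuffled genome is supplied, the same search is run on it and the
#' per-family threshold Z0 is calibrated so the FDR stays within
#' \code{config$fdrMax}; only hits with Z >= Z0 are returned.
#'
#' @param genome a \code{GenomeIndex}.
#' @param family a \code{RepeatFamily} (or a \code{RepeatPWM}).
#' @param config an \code{\link{ipConfig}}.
#' @param shuffled optional shuffled \code{GenomeIndex} for FDR
#'   calibration.
#' @param respectMask if TRUE, windows over masked bases are skipped;
#'   by default the final search sees the whole genome.
#' @param seed seed for the null subsamples.
#' @return list with \code{hits} (GRanges, both strands), \code{Z0},
#'   \code{fdr} (data.frame, empty without \code{shuffled}).
#' @export
searchFamily <- function(genome, family, config, shuffled = NULL,
                         respectMask = FALSE, seed = NULL) {
    pwm <- if (is(family, "RepeatFamily")) family@pwm else family
    famId <- if (is(family, "RepeatFamily")) family@id else NA_integer_
    g <- genome
    if (!respectMask && any(g@mask))
        g <- new("GenomeIndex", seq = g@seq, records = g@records,
                 baseFreq = g@baseFreq,
                 mask = rep(FALSE, genomeLength(g)))
    calib_g <- if (is.null(shuffled)) shuffleGenome(g, seed = .childSeed(
        if (is.null(seed)) 1L else seed, 99L)) else shuffled
    z0min <- min(config$fdrGrid)
    one_strand <- function(mat, strand, source) {
        null <- calibrateNull(calib_g, mat, config, seed = seed)
        prof <- zTransform(scanGenome(g, mat, config), null)
        maxima <- localMaxima(prof, z0min, config$halfwidth)
        hits <- if (nrow(maxima))
            .hitsFromTraces(g, .tracesAtMaxima(g, mat, config, maxima),
                            family = famId, strand = strand,
                            source = source)
        else GRanges()
        shufZ <- if (!is.null(shuffled)) {
            nprof <- zTransform(scanGenome(shuffled, mat, config), null)
            localMaxima(nprof, z0min, config$halfwidth)$Z
        } else numeric(0)
        list(hits = hits, shufZ = shufZ)
    }
    dir <- one_strand(pwm, "+", "direct")
    inv <- one_strand(invertPWM(pwm), "-", "inverted")
    hits <- suppressWarnings(c(dir$hits, inv$hits))
    Z0 <- NA_real_
    fdr <- data.frame()
    if (!is.null(shuffled)) {
        realZ <- mcols(hits)$Z
        shufZ <- c(dir$shufZ, inv$shufZ)
        tp <- vapply(config$fdrGrid, function(z) sum(realZ >= z), 0L)
        fp <- vapply(config$fdrGrid, function(z) sum(shufZ >= z), 0L)
        cal <- calibrateFDR(tp, fp, config$fdrGrid, config$fdrMax)
        Z0 <- cal$Z0
        fdr <- cal$table
        hits <- hits[mcols(hits)$Z >= Z0]
    }
    list(hits = hits, Z0 = Z0, fdr = fdr)
}

#' FDR calibration over a threshold grid
#'
#' FDR(Z0) = FP / (FP + TP), where TP is the hit count in the real genome
#' and FP the hit count in the shuffled genome at threshold Z0.  The
#' per-family threshold is the smallest grid value whose FDR is within
#' \code{fdrMax}; if none qualifies the largest grid value is used and a
#' warning is raised.
#'
#' @param tp,fp integer hit counts per grid value (scalars are allowed for
#'   a single-point table).
#' @param grid threshold grid.
#' @param fdrMax admissible FDR.
#' @return list with \code{Z0}, \code{table} (data.frame Z0/TP/FP/FDR) and
#'   \code{ok} (whether the bound was met).
#' @export
calibrateFDR <- function(tp, fp, grid = seq(5, 8, by = 0.5),
                         fdrMax = 0.04) {
    stopifnot(length(tp) == length(fp))
    if (length(grid) != length(tp)) grid <- grid[seq_along(tp)]
    denom <- fp + tp
    fdr <- ifelse(denom > 0, fp / denom, 0)
    tab <- data.frame(Z0 = grid, TP = tp, FP = fp, FDR = fdr)
    ok <- which(fdr <= fdrMax)
    if (length(ok)) {
        list(Z0 = grid[ok[1L]], table = tab, ok = TRUE)
    } else {
        warning("no grid threshold reaches FDR <= ", fdrMax,
                "; using the largest grid value")
        list(Z0 = grid[length(grid)], table = tab, ok = FALSE)
    }
}

#' Resolve overlapping hits across families
#'
#' Hits of the same strand class sharing more than \code{minShared} common
#' bases compete; within every connected group of such overlaps only the
#' hit with the largest Z survives (greedy by descending Z, ties broken by
#' earlier start then lower family id).  Hits sharing exactly
#' \code{minShared} bases or fewer are not considered overlapping.
#'
#' @param hits \code{GRanges} with metadata columns \code{Z} and
#'   \code{family}.
#' @param minShared overlap strictly above this many bases triggers
#'   competition (default 50).
#' @return the surviving hits, original order preserved.
#' @export
resolveOverlaps <- function(hits, minShared = 50L) {
    if (length(hits) < 2L) return(hits)
    keep <- rep(TRUE, length(hits))
    for (str in unique(as.character(strand(hits)))) {
        idx <- which(as.character(strand(hits)) == str)
        if (length(idx) < 2L) next
        h <- hits[idx]
        ov <- findOverlaps(h, minoverlap = minShared + 1L,
                           drop.self = TRUE, drop.redundant = FALSE)
        if (!length(ov)) next
        ord <- order(-mcols(h)$Z, start(h), mcols(h)$family)
        alive <- rep(TRUE, length(h))
        nb <- split(subjectHits(ov), queryHits(ov))
        for (q in ord) {
            if (!alive[q]) next
            ns <- nb[[as.character(q)]]
            if (!is.null(ns)) alive[ns] <- FALSE
        }
        keep[idx] <- alive
    }
    hits[keep]
}
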