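#' Pipeline configuration
#'
#' Collects every tunable parameter of the discovery pipeline.  The
#' defaults are the full-scale settings used for whole-genome runs: 16 x
#' 600 matrices scanned through a 650-base window every 10 bases, the
#' significance schedule Z0 = 3.0 on the first refinement pass and 5.0
#' afterwards, 20 refinement iterations over 50 random start matrices, a
#' minimum family size of 300 and a 4\% FDR budget.  \code{profile =
#' "desk"} shrinks only the compute-sizing knobs (stride, iteration and
#' matrix counts, null subsample) so the same science runs at workstation
#' scale.
#'
#' @param L number of matrix columns.
#' @param window scan window length in bases (>= L).
#' @param step scan stride in bases.
#' @param R0sq target weighted second moment of a transformed matrix;
#'   default 300 * sqrt(L).
#' @param K0 target weighted mean matrix element; default -1.
#' @param Z0first significance threshold for the first refinement pass.
#' @param Z0iter significance threshold for subsequent passes.
#' @param halfwidth local-maximum domination half-width, in scan steps.
#'   The default tracks the stride so the dominated neighborhood stays
#'   about +/- 650 bases.
#' @param nIterations refinement iterations per start matrix.
#' @param nMatrices number of random start matrices per discovery round.
#' @param iMin iterations discarded as burn-in when picking the best
#'   iteration (the best iteration must satisfy i > iMin).
#' @param Nmin minimum member count for a family to be accepted.
#' @param fdrMax FDR bound used to pick the per-family threshold Z0.
#' @param fdrGrid candidate per-family Z0 thresholds.
#' @param gapPenalty linear gap penalty per symbol, in score units of the
#'   transformed matrix (whose per-cell standard deviation is
#'   sqrt(R0sq / (16 L)), about 0.87 at the defaults).
#' @param nullWindows number of shuffled-genome windows used to estimate
#'   the null mean and standard deviation (all windows if fewer exist).
#' @param maxNfrac windows with at least this fraction of ambiguous (N)
#'   bases are skipped.
#' @param traceMode register used for the member traces that rebuild the
#'   frequency matrix: \code{"fit"} (default) lets every member choose its
#'   column register freely so member phases can converge across
#'   iterations; \code{"anchored"} pins traces to the window start.
#' @param scanMode scan statistic: \code{"anchored"} (default) scores the
#'   fit of all matrix columns starting at the window's first base, so
#'   F(t) peaks sharply where a repeat begins and member traces share one
#'   column register; \code{"local"} uses the Smith-Waterman style local
#'   score.
#' @param maxFamilies safety cap on accepted families per run.
#' @param profile \code{"full"} or \code{"desk"}.
#' @param ... overrides applied after the profile.
#' @return a list of class \code{ipConfig}.
#' @export
ipConfig <- function(L = 600L, window = 650L, step = 10L,
                     R0sq = NULL, K0 = -1,
                     Z0first = 3.0, Z0iter = 5.0, halfwidth = NULL,
                     nIterations = 20L, nMatrices = 50L, iMin = 8L,
                     Nmin = 300L, fdrMax = 0.04,
                     fdrGrid = seq(5, 8, by = 0.5),
                     gapPenalty = 5.0,
                     nullWindows = 10000L, maxNfrac = 0.1,
                     scanMode = c("anchored", "local"),
                     traceMode = c("fit", "anchored"),
                     maxFamilies = 30L,
                     profile = c("full", "desk"), ...) {
    scanMode <- match.arg(scanMode)
    traceMode <- match.arg(traceMode)
    profile <- match.arg(profile)
    if (profile == "desk") {
        # workstation sizing: same science, coarser stride, fewer chains;
        # explicit arguments always win over the profile
        if (missing(step)) step <- 20L
        if (missing(nIterations)) nIterations <- 10L
        if (missing(nMatrices)) nMatrices <- 3L
        if (missing(nullWindows)) nullWindows <- 1000L
    }
    cfg <- list(L = as.integer(L), window = as.integer(window),
                step = as.integer(step),
                R0sq = if (is.null(R0sq)) 300 * sqrt(L) else R0sq,
                K0 = K0, Z0first = Z0first, Z0iter = Z0iter,
                halfwidth = if (is.null(halfwidth))
                    as.integer(round(650 / step)) else as.integer(halfwidth),
                nIterations = as.integer(nIterations),
                nMatrices = as.integer(nMatrices), iMin = as.integer(iMin),
                Nmin = as.integer(Nmin), fdrMax = fdrMax, fdrGrid = fdrGrid,
                gapPenalty = gapPenalty,
                nullWindows = as.integer(nullWindows), maxNfrac = maxNfrac,
                scanMode = scanMode, traceMode = traceMode,
                maxFamilies = as.integer(maxFamilies), profile = profile)
    over <- list(...)
    if (length(over)) {
        bad <- setdiff(names(over), names(cfg))
        if (length(bad)) stop("unknown config fields: ",
                              paste(bad, collapse = ", "))
        cfg[names(over)] <- over
    }
    .validateConfig(cfg)
    class(cfg) <- "ipConfig"
    cfg
}

.validateConfig <- function(cfg) {
    stopifnot(cfg$L >= 2L, cfg$window >= cfg$L, cfg$step >= 1L,
              cfg$R0sq > cfg$K0^2, cfg$halfwidth >= 1L,
              cfg$nIterations >= 1L, cfg$nMatrices >= 1L,
              cfg$iMin >= 0L, cfg$Nmin >= 1L,
              cfg$fdrMax >= 0, cfg$fdrMax <= 1,
              cfg$gapPenalty > 0, cfg$maxNfrac > 0)
    invisible(TRUE)
}

#' @export
print.ipConfig <- function(x, ...) {
    cat("ipConfig (", x$profile, " profile)\n", sep = "")
    cat(sprintf("  matrix 16 x %d, window %d, step %d\n",
                x$L, x$window, x$step))
    cat(sprintf("  R0^2 = %.2f, K0 = %g, gap penalty %.2f\n",
                x$R0sq, x$K0, x$gapPenalty))
    cat(sprintf("  Z0 schedule %.1f then %.1f, %d iterations x %d matrices, Nmin %d, FDR <= %.1f%%\n",
                x$Z0first, x$Z0iter, x$nIterations, x$nMatrices,
                x$Nmin, 100 * x$fdrMax))
    invisible(x)
}

# Deterministic child seed derivation (Lehmer step), kept below 2^31.
.childSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 48271 + 11 * as.numeric(k) + 1) %%
               2147483629)
}

# Evaluate expr under a temporary RNG state seeded with `seed`
# (restores the caller's RNG stream afterwards).
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
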