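#' Scan a genome with a PWM
#'
#' Slides a window of \code{config$window} bases along the concatenated
#' genome with stride \code{config$step} and records the local-alignment
#' score F(t) of every window, t = 1, 2, ... with window start
#' x = (t-1) step + 1.  Windows touching a masked base, or containing at
#' least \code{config$maxNfrac} ambiguous bases, are flagged and given
#' F = 0 without alignment (their Z is forced to 0 downstream).
#'
#' @param genome a \code{GenomeIndex}.
#' @param pwm a \code{RepeatPWM}.
#' @param config an \code{\link{ipConfig}}.
#' @param starts optional explicit 1-based window starts (used for null
#'   subsampling); default is the full grid.
#' @return a list of class \code{ScanProfile}: \code{t}, \code{x}
#'   (window starts), \code{F}, \code{flagged}, plus the scan geometry.
#' @export
scanGenome <- function(genome, pwm, config, starts = NULL) {
    LS <- genomeLength(genome)
    if (LS < config$window) stop("genome shorter than the scan window")
    if (is.null(starts))
        starts <- seq.int(1L, LS - config$window + 1L, by = config$step)
    res <- .cpp_scan(genome@seq, genome@mask, pwm@weights,
                     config$gapPenalty, config$window, config$maxNfrac,
                     as.integer(starts - 1L),
                     identical(config$scanMode, "anchored"))
    out <- list(t = seq_along(starts), x = as.integer(starts),
                F = res$F, flagged = res$flagged,
                window = config$window, step = config$step)
    class(out) <- "ScanProfile"
    out
}

#' @export
print.ScanProfile <- function(x, ...) {
    cat("ScanProfile:", length(x$F), "windows of", x$window,
        "bases, step", x$step, "\n")
    cat(sprintf("  F: mean %.2f, max %.2f; %d flagged\n",
                mean(x$F[!x$flagged]), max(x$F), sum(x$flagged)))
    if (!is.null(x$Z))
        cat(sprintf("  Z: max %.2f\n", max(x$Z)))
    invisible(x)
}

#' Calibrate the null score distribution on a shuffled genome
#'
#' Estimates the mean and standard deviation of F over windows of the
#' shuffled genome; all windows are used when fewer than \code{nWindows}
#' exist, otherwise a seeded random subsample of window starts.
#'
#' @param shuffled a shuffled \code{GenomeIndex} (same base composition as
#'   the target genome).
#' @param pwm a \code{RepeatPWM}.
#' @param config an \code{\link{ipConfig}}.
#' @param nWindows subsample size (default \code{config$nullWindows}).
#' @param seed seed for the subsample.
#' @return a list of class \code{NullCalibration}: \code{mean}, \code{sd},
#'   \code{n}, \code{seed}.
#' @export
calibrateNull <- function(shuffled, pwm, config,
                          nWindows = config$nullWindows, seed = NULL) {
    LS <- genomeLength(shuffled)
    all_starts <- seq.int(1L, LS - config$window + 1L, by = config$step)
    starts <- if (length(all_starts) <= nWindows) all_starts
        else .withSeed(seed, sort(sample(all_starts, nWindows)))
    prof <- scanGenome(shuffled, pwm, config, starts = starts)
    f <- prof$F[!prof$flagged]
    if (length(f) < 2L) stop("too few null windows to calibrate")
    s <- sd(f)
    if (!is.finite(s) || s <= 0)
        stop("degenerate null profile: zero score variance")
    out <- list(mean = mean(f), sd = s, n = length(f),
                seed = if (is.null(seed)) NA_integer_ else seed)
    class(out) <- "NullCalibration"
    out
}

#' @export
print.NullCalibration <- function(x, ...) {
    cat(sprintf("NullCalibration: F mean %.3f, sd %.3f (n = %d windows)\n",
                x$mean, x$sd, x$n))
    invisible(x)
}

#' Standardize a scan profile against a null calibration
#'
#' Z(t) = (F(t) - Fbar) / sigma(F); flagged windows (masked bases or too
#' many Ns) are forced to Z = 0 so they can never seed or extend a family.
#'
#' @param profile a \code{ScanProfile}.
#' @param null a \code{NullCalibration}.
#' @return the profile with a \code{Z} component added.
#' @export
zTransform <- function(profile, null) {
    z <- (profile$F - null$mean) / null$sd
    z[profile$flagged] <- 0
    profile$Z <- z
    profile
}

#' Significant local maxima of a scan profile
#'
#' A point t is a local maximum when F(t) dominates every neighbour within
#' \code{halfwidth} steps on both sides (missing neighbours at the profile
#' boundary cannot veto).  Of a plateau of equal values within the
#' half-width only the leftmost point is reported.  Maxima must additionally
#' pass Z(t) > Z0.
#'
#' @param profile a \code{ScanProfile} with Z computed.
#' @param Z0 significance threshold.
#' @param halfwidth domination half-width in steps.
#' @return data.frame with columns t, x, F, Z.
#' @export
localMaxima <- function(profile, Z0, halfwidth) {
    stopifnot(!is.null(profile$Z))
    f <- profile$F
    rm_ <- .cpp_run_max(f, as.integer(halfwidth))
    cand <- which(f == rm_ & profile$Z > Z0)
    if (length(cand) > 1L) {
        # leftmost representative of each plateau: drop a candidate whose
        # previous equal-valued candidate lies within the half-width
        keep <- rep(TRUE, length(cand))
        last_kept <- 1L
        for (k in 2:length(cand)) {
            if (cand[k] - cand[last_kept] <= halfwidth &&
                f[cand[k]] == f[cand[last_kept]]) {
                keep[k] <- FALSE
            } else last_kept <- k
        }
        cand <- cand[keep]
    }
    data.frame(t = profile$t[cand], x = profile$x[cand],
               F = f[cand], Z = profile$Z[cand])
}
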