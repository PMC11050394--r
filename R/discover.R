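# Re-align the scan window at each maximum.  The fit alignment (all
# matrix columns consumed) supplies s1/s2 for frequency-matrix counting,
# keeping members in a common column register; the local alignment
# defines the genomic span the hit actually covers (concatenated coords).
.tracesAtMaxima <- function(genome, pwm, config, maxima) {
    lapply(seq_len(nrow(maxima)), function(k) {
        x <- maxima$x[k]
        codes <- genome@seq[x:(x + config$window - 1L)]
        tr <- .cpp_align_fit(codes, pwm@weights, config$gapPenalty,
                             identical(config$traceMode, "anchored"))
        loc <- .cpp_align_trace(codes, pwm@weights, config$gapPenalty)
        if (is.na(loc$first)) {
            loc$first <- tr$first
            loc$last <- tr$last
        }
        tr$wstart <- x
        tr$start <- if (is.na(loc$first)) NA_integer_ else x + loc$first - 1L
        tr$end <- if (is.na(loc$last)) NA_integer_ else x + loc$last - 1L
        tr$Z <- maxima$Z[k]
        tr
    })
}

# Right-align the matrix's strongly informative block.  The anchored
# scan reads a window forward from the element's anchor, so a register
# that starts mid-element can never learn the element's 5' head (the
# trailing columns fill with weakly self-consistent noise instead).
# When the per-column information profile shows a clear strong block
# that ends before the last column, the columns are rolled right so the
# block ends at column L: the next iteration's maxima shift to the
# element start and the vacated leading columns (neutral, K0) are
# re-estimated from the element's head.
.rollRegister <- function(MAT, mt, config) {
    # per-column chi-square against the dinucleotide background
    y <- colSums(MAT)
    E <- outer(mt@p1, y)
    ok <- E > 0
    dev <- matrix(0, nrow(MAT), ncol(MAT))
    dev[ok] <- (MAT[ok] - E[ok])^2 / E[ok]
    info <- colSums(dev)
    if (config$L >= 9L) info <- stats::runmed(info, 9L)
    hi <- stats::quantile(info, 0.95)
    if (hi <= 2.5 * stats::median(info)) return(mt)   # no clear block
    K <- max(which(info > 0.4 * hi))
    delta <- config$L - K
    if (delta <= max(10L, config$L %/% 24L)) return(mt)
    w <- pwmWeights(mt)
    w2 <- cbind(matrix(config$K0, 16L, delta), w[, seq_len(K), drop = FALSE])
    transformPWM(w2, mt@p1, config$R0sq, config$K0)
}

#' Iteratively refine a start matrix against a genome
#'
#' One chain of the iterative procedure: scan the genome with the current
#' matrix, standardize against the shuffled-genome null, keep significant
#' local maxima (Z0 = \code{Z0first} on the first pass, \code{Z0iter}
#' afterwards), re-align the maxima windows, accumulate the dinucleotide
#' frequency matrix, standardize it and re-constrain it into the next
#' matrix.  The null is recalibrated whenever the matrix changes.
#'
#' @param genome target \code{GenomeIndex} (possibly partially masked).
#' @param shuffled shuffled \code{GenomeIndex} for the null.
#' @param mt0 transformed start \code{RepeatPWM}.
#' @param config an \code{\link{ipConfig}}.
#' @param seed integer seed driving the null subsamples.
#' @return list of per-iteration records (class \code{ipChain}); each has
#'   \code{i}, \code{Nz}, \code{maxima} (data.frame), \code{traces},
#'   \code{pwm} (the matrix that produced the maxima) and \code{null}.
#' @export
refineMatrix <- function(genome, shuffled, mt0, config, seed = NULL) {
    mt <- mt0
    records <- vector("list", config$nIterations)
    for (i in seq_len(config$nIterations)) {
        Z0 <- if (i == 1L) config$Z0first else config$Z0iter
        null <- calibrateNull(shuffled, mt, config,
                              seed = if (is.null(seed)) NULL
                                     else .childSeed(seed, i))
        prof <- zTransform(scanGenome(genome, mt, config), null)
        maxima <- localMaxima(prof, Z0, config$halfwidth)
        if (nrow(maxima) == 0L) {
            records[[i]] <- list(i = i, Nz = 0L,
                                 maxima = maxima, traces = list(),
                                 pwm = mt, null = null)
            records <- records[seq_len(i)]
            break
        }
        traces <- .tracesAtMaxima(genome, mt, config, maxima)
        records[[i]] <- list(i = i, Nz = nrow(maxima), maxima = maxima,
                             traces = traces, pwm = mt, null = null)
        MAT <- accumulateMAT(traces, config$L)
        if (sum(MAT) == 0L) {
            records <- records[seq_len(i)]
            break
        }
        M <- standardizeCounts(MAT)
        mt <- transformPWM(M, mt@p1, config$R0sq, config$K0)
        mt <- .rollRegister(MAT, mt, config)
    }
    records <- records[!vapply(records, is.null, logical(1))]
    class(records) <- "ipChain"
    records
}

#' Select the best iteration and chain
#'
#' Within each chain only iterations i > \code{iMin} are eligible (early
#' iterations fluctuate sharply); the eligible iteration with the largest
#' member count N_z wins, earliest iteration on ties.  Across chains the
#' largest N_z(i_max) wins, lowest chain index on ties.
#'
#' @param chains list of chains from \code{\link{refineMatrix}}.
#' @param iMin burn-in bound (default 8).
#' @return list with \code{chain}, \code{iMax}, \code{Nmax}, \code{pwm},
#'   \code{maxima}, \code{traces}; or NULL when no chain has an eligible
#'   iteration with N_z > 0.
#' @export
selectBest <- function(chains, iMin = 8L) {
    best <- NULL
    for (ci in seq_along(chains)) {
        ch <- chains[[ci]]
        idx <- which(vapply(ch, function(r) r$i, 0L) > iMin)
        if (!length(idx)) next
        nz <- vapply(ch[idx], function(r) r$Nz, 0L)
        if (max(nz) == 0L) next
        k <- idx[which.max(nz)]
        if (is.null(best) || ch[[k]]$Nz > best$Nmax) {
            best <- list(chain = ci, iMax = ch[[k]]$i,
                         Nmax = ch[[k]]$Nz, pwm = ch[[k]]$pwm,
                         maxima = ch[[k]]$maxima, traces = ch[[k]]$traces)
        }
    }
    best
}

# Hit GRanges (record coordinates) from the traces of accepted maxima.
.hitsFromTraces <- function(genome, traces, family = NA_integer_,
                            strand = "+", source = "direct") {
    ok <- vapply(traces, function(tr) !is.na(tr$start), logical(1))
    traces <- traces[ok]
    if (!length(traces))
        return(GRanges())
    st <- vapply(traces, function(tr) tr$start, 0L)
    en <- vapply(traces, function(tr) tr$end, 0L)
    z <- vapply(traces, function(tr) tr$Z, 0)
    ws <- vapply(traces, function(tr) tr$wstart, 0L)
    loc <- concatToRecord(genome, st)
    loc2 <- concatToRecord(genome, en)
    # alignments never span record boundaries in practice; clip if one does
    en_rec <- ifelse(loc2$record == loc$record, loc2$pos,
                     genomeRecords(genome)$length[
                         match(loc$record, genomeRecords(genome)$name)])
    gr <- GRanges(loc$record, IRanges(loc$pos, en_rec), strand = strand)
    sl <- setNames(genomeRecords(genome)$length, genomeRecords(genome)$name)
    seqlevels(gr) <- names(sl)
    seqlengths(gr) <- sl
    mcols(gr)$Z <- z
    mcols(gr)$wstart <- ws
    mcols(gr)$family <- family
    mcols(gr)$source <- source
    gr
}

#' Discover dispersed repeat families
#'
#' Runs the full iterative procedure: in each round,
#' \code{config$nMatrices} random start matrices are refined for
#' \code{config$nIterations} iterations each, the best chain/iteration is
#' selected, and its family is accepted when its member count exceeds
#' \code{config$Nmin}.  The aligned bases of an accepted family are masked
#' and the next round searches the remainder; discovery stops at the first
#' round whose best family is not larger than \code{Nmin}.
#'
#' @param genome a \code{GenomeIndex}.
#' @param config an \code{\link{ipConfig}}.
#' @param seed master seed; all per-matrix and null seeds derive from it.
#' @param verbose print per-round progress.
#' @return list of \code{RepeatFamily} objects (possibly empty).
#' @export
discoverFamilies <- function(genome, config, seed = 1L, verbose = FALSE) {
    shuffled <- shuffleGenome(genome, seed = .childSeed(seed, 0L))
    p1 <- .dinucBackground(baseFrequencies(genome))
    families <- list()
    g <- genome
    round <- 0L
    repeat {
        round <- round + 1L
        chains <- vector("list", config$nMatrices)
        for (m in seq_len(config$nMatrices)) {
            mseed <- .childSeed(seed, 1000L * round + m)
            mt0 <- transformPWM(randomPWM(config$L, seed = mseed), p1,
                                config$R0sq, config$K0)
            chains[[m]] <- refineMatrix(g, shuffled, mt0, config,
                                        seed = mseed)
            if (verbose)
                message(sprintf("round %d matrix %d: Nz = %s", round, m,
                                paste(vapply(chains[[m]],
                                             function(r) r$Nz, 0L),
                                      collapse = " ")))
        }
        best <- selectBest(chains, config$iMin)
        if (is.null(best) || best$Nmax <= config$Nmin) break
        id <- length(families) + 1L
        hits <- .hitsFromTraces(g, best$traces, family = id)
        fam <- new("RepeatFamily", id = id, pwm = best$pwm,
                   Nmax = as.integer(best$Nmax),
                   iMax = as.integer(best$iMax), hits = hits,
                   Z0 = NA_real_, fdr = data.frame())
        families[[id]] <- fam
        spans <- cbind(start = vapply(best$traces, function(tr) tr$start, 0L),
                       end = vapply(best$traces, function(tr) tr$end, 0L))
        spans <- spans[!is.na(spans[, 1L]), , drop = FALSE]
        g <- applyMask(g, spans)
        if (verbose)
            message(sprintf("accepted family %d: N = %d (iteration %d); %d bp masked",
                            id, best$Nmax, best$iMax, maskedBases(g)))
        if (length(families) >= config$maxFamilies) break
    }
    families
}

#' RepeatFamily accessors
#' @param family a \code{RepeatFamily}.
#' @return \code{familyPWM}: the accepted matrix; \code{familyHits}: the
#'   member hits \code{GRanges}; \code{familySize}: member count.
#' @export
familyPWM <- function(family) family@pwm

#' @rdname familyPWM
#' @export
familyHits <- function(family) family@hits

#' @rdname familyPWM
#' @export
familySize <- function(family) family@Nmax
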