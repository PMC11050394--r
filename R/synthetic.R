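# Mutate a mother sequence (integer codes) into one diverged copy:
# nSub substitution events at random positions (with replacement, so a
# site can be hit repeatedly and divergence saturates), each event
# changing the base to one of the other three; then nIndel indels
# (insertion/deletion 50/50) of size 1..5 at random positions.
.mutateCopy <- function(mother, nSub, nIndel, indelSizes = 1:5) {
    s <- mother
    La <- length(s)
    if (nSub > 0) {
        pos <- sample.int(La, nSub, replace = TRUE)
        shift <- sample.int(3L, nSub, replace = TRUE)
        for (q in seq_len(nSub))
            s[pos[q]] <- (s[pos[q]] + shift[q]) %% 4L
    }
    identity <- mean(s == mother)
    if (nIndel > 0) {
        for (q in seq_len(nIndel)) {
            sz <- sample(indelSizes, 1L)
            if (runif(1) < 0.5 && length(s) > sz + 1L) {      # deletion
                at <- sample.int(length(s) - sz + 1L, 1L)
                s <- s[-(at:(at + sz - 1L))]
            } else {                                          # insertion
                at <- sample.int(length(s) + 1L, 1L)
                s <- append(s, sample(0:3, sz, replace = TRUE), after = at - 1L)
            }
        }
    }
    attr(s, "identity") <- identity
    s
}

# Place copy sequences at random non-overlapping positions with at least
# minGap background bases between and around them; background is i.i.d.
# over `freq`.  Returns genome codes and a truth data.frame.
.assembleGenome <- function(copies, totalLength, minGap, freq) {
    n <- length(copies)
    lens <- lengths(copies)
    slack <- totalLength - sum(lens) - minGap * (n + 1L)
    if (slack < 0)
        stop("genome too short to place ", n, " copies with the ",
             "requested gap")
    # random composition of the slack into n+1 gap increments
    cuts <- sort(sample.int(slack + n, n))
    extra <- diff(c(0L, cuts, slack + n + 1L)) - 1L
    gaps <- minGap + extra
    bg <- function(len) sample(0:3, len, replace = TRUE, prob = freq)
    parts <- vector("list", 2L * n + 1L)
    truth <- data.frame(start = integer(n), end = integer(n))
    pos <- 0L
    for (k in seq_len(n)) {
        parts[[2L * k - 1L]] <- bg(gaps[k])
        pos <- pos + gaps[k]
        truth$start[k] <- pos + 1L
        pos <- pos + lens[k]
        truth$end[k] <- pos
        parts[[2L * k]] <- copies[[k]]
    }
    parts[[2L * n + 1L]] <- bg(gaps[n + 1L])
    list(seq = unlist(parts), truth = truth)
}

#' Generate a genome with one planted diverged repeat family
#'
#' Plants \code{nCopies} diverged copies of a random mother sequence of
#' \code{repeatLength} bases in i.i.d. background.  Each copy carries
#' round(0.5 x repeatLength) random substitution events (positions drawn
#' with replacement, so two copies accumulate x substitutions per
#' nucleotide between them while the realized sequence divergence
#' saturates as in finite-alphabet evolution) and a
#' Poisson(repeatLength / 50) number of indels of random size 1-5.
#' Copies are placed at random non-overlapping positions separated by at
#' least \code{minGap} background bases; the realized per-copy identity to
#' the mother is recorded in the truth object.
#'
#' @param length total genome length in bases.
#' @param repeatLength mother sequence length L_a.
#' @param nCopies number of planted copies N_a.
#' @param x target divergence (substitutions per nucleotide between two
#'   copies).
#' @param seed integer seed (the full construction is deterministic).
#' @param minGap minimum background gap between copies.  The default keeps
#'   copies isolated at the scale of the scan window, as they are in a
#'   large genome, so no window spans substantial parts of two copies.
#' @param background base frequencies of the background (a, t, c, g).
#' @param mother optional mother sequence (character) to reuse.
#' @return a \code{\link{PlantedGenome}}.
#' @export
makePlantedGenome <- function(length = 4e6, repeatLength = 600L,
                              nCopies = 500L, x = 1.0, seed = NULL,
                              minGap = 400L,
                              background = rep(0.25, 4), mother = NULL) {
    .withSeed(seed, {
        mcodes <- if (is.null(mother)) sample(0:3, repeatLength, TRUE)
            else .encodeDNA(mother)
        nSub <- round(0.5 * x * repeatLength)
        nInd <- rpois(nCopies, repeatLength / 50)
        copies <- lapply(seq_len(nCopies),
                         function(k) .mutateCopy(mcodes, nSub, nInd[k]))
        asm <- .assembleGenome(copies, as.integer(length), minGap,
                               background)
        g <- genomeIndexFromSequence(asm$seq, names = "chr1")
        truth <- GRanges("chr1", IRanges(asm$truth$start, asm$truth$end),
                         strand = "+")
        seqlengths(truth) <- c(chr1 = genomeLength(g))
        mcols(truth)$family <- 1L
        mcols(truth)$nSub <- nSub
        mcols(truth)$nIndel <- nInd
        mcols(truth)$motherIdentity <-
            vapply(copies, function(s) attr(s, "identity"), 0)
        new("PlantedGenome", genome = g, truth = truth,
            mothers = .decodeDNA(mcodes),
            params = list(length = length, repeatLength = repeatLength,
                          nCopies = nCopies, x = x, minGap = minGap,
                          seed = seed))
    })
}

#' Generate a genome with two planted families at controlled divergence
#'
#' Two mother sequences are derived from a common ancestor, each by
#' round(0.5 xBetween L_a) substitution events, so their expected mutual
#' divergence is \code{xBetween} substitutions per nucleotide.  Each
#' family consists of \code{nCopies} exact copies of its mother,
#' interleaved at random non-overlapping positions.
#'
#' @param xBetween divergence between the two mothers.
#' @param nCopies copies per family.
#' @param repeatLength mother length.
#' @param length total genome length; default sized so roughly a quarter
#'   of the genome is background.
#' @param seed integer seed.
#' @param minGap minimum background gap between copies.
#' @return a \code{\link{PlantedGenome}} with truth families 1 and 2.
#' @export
makeTwoFamilyGenome <- function(xBetween, nCopies = 250L,
                                repeatLength = 600L, length = NULL,
                                seed = NULL, minGap = 400L) {
    if (is.null(length))
        length <- as.integer(round(2 * nCopies * (repeatLength + minGap) * 1.06))
    .withSeed(seed, {
        anc <- sample(0:3, repeatLength, TRUE)
        nSub <- round(0.5 * xBetween * repeatLength)
        mutate <- function() {
            s <- anc
            if (nSub > 0) {
                # substitution events with replacement: coincident events
                # at one site are allowed, divergence saturates naturally
                pos <- sample.int(repeatLength, nSub, replace = TRUE)
                shift <- sample.int(3L, nSub, replace = TRUE)
                for (q in seq_len(nSub))
                    s[pos[q]] <- (s[pos[q]] + shift[q]) %% 4L
            }
            s
        }
        mothers <- list(mutate(), mutate())
        fam <- sample(rep(1:2, each = nCopies))
        copies <- lapply(fam, function(f) mothers[[f]])
        asm <- .assembleGenome(copies, as.integer(length), minGap,
                               rep(0.25, 4))
        g <- genomeIndexFromSequence(asm$seq, names = "chr1")
        truth <- GRanges("chr1", IRanges(asm$truth$start, asm$truth$end),
                         strand = "+")
        seqlengths(truth) <- c(chr1 = genomeLength(g))
        mcols(truth)$family <- fam
        mcols(truth)$nSub <- 0L
        mcols(truth)$nIndel <- 0L
        new("PlantedGenome", genome = g, truth = truth,
            mothers = c(.decodeDNA(mothers[[1L]]),
                        .decodeDNA(mothers[[2L]])),
            params = list(length = length, repeatLength = repeatLength,
                          nCopies = nCopies, x = xBetween,
                          minGap = minGap, seed = seed))
    })
}

#' Score recovered repeats against the planted truth
#'
#' A planted copy counts as recovered when some hit overlaps it by
#' strictly more than \code{matchFraction} of the copy's length; a hit is
#' a false positive when no copy overlaps it by more than
#' \code{matchFraction} of the hit's length.  For each found family the
#' purity is the largest fraction of its truth-matched hits tracing to a
#' single mother family.
#'
#' @param hits found repeat \code{GRanges} (metadata column \code{family}
#'   optional).
#' @param truth planted truth \code{GRanges} (metadata column
#'   \code{family}) or a \code{PlantedGenome}.
#' @param matchFraction overlap fraction (default 0.5).
#' @return list with \code{sensitivity}, \code{fdr}, \code{nRecovered},
#'   \code{nPlanted}, \code{nHits}, \code{purity} (per found family) and
#'   \code{confusion} (found family x planted family counts).
#' @export
evaluateRecovery <- function(hits, truth, matchFraction = 0.5) {
    if (is(truth, "PlantedGenome")) truth <- truth@truth
    nP <- length(truth)
    nH <- length(hits)
    if (nH == 0L)
        return(list(sensitivity = 0, fdr = NA_real_, nRecovered = 0L,
                    nPlanted = nP, nHits = 0L,
                    purity = numeric(0),
                    confusion = table(found = integer(0),
                                      planted = integer(0))))
    ov <- findOverlaps(hits, truth, ignore.strand = TRUE)
    w <- width(pintersect(ranges(hits)[queryHits(ov)],
                          ranges(truth)[subjectHits(ov)]))
    recMask <- w > matchFraction * width(truth)[subjectHits(ov)]
    recovered <- unique(subjectHits(ov)[recMask])
    hitMatch <- w > matchFraction * width(hits)[queryHits(ov)]
    matched_hits <- unique(queryHits(ov)[hitMatch])
    fdr <- 1 - length(matched_hits) / nH
    foundFam <- mcols(hits)$family
    if (is.null(foundFam)) foundFam <- rep(1L, nH)
    plantedFam <- mcols(truth)$family
    if (is.null(plantedFam)) plantedFam <- rep(1L, nP)
    pair <- data.frame(found = foundFam[queryHits(ov)[hitMatch]],
                       planted = plantedFam[subjectHits(ov)[hitMatch]])
    confusion <- table(found = pair$found, planted = pair$planted)
    purity <- if (nrow(confusion))
        apply(confusion, 1L, function(r) if (sum(r) > 0)
            max(r) / sum(r) else NA_real_)
        else numeric(0)
    list(sensitivity = length(recovered) / nP, fdr = fdr,
         nRecovered = length(recovered), nPlanted = nP, nHits = nH,
         purity = purity, confusion = confusion)
}
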