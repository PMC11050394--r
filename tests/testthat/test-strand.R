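test_that("FDR calibration reproduces the printed arithmetic", {
    # single-point tables at Z0 = 5
    one <- calibrateFDR(tp = 4465L, fp = 48L, grid = 5.0)
    expect_equal(one$table$FDR, 48 / (48 + 4465))
    expect_equal(round(100 * one$table$FDR, 2), 1.06)
    tot <- calibrateFDR(tp = 33938L, fp = 552L, grid = 5.0)
    expect_equal(round(100 * tot$table$FDR, 2), 1.60)
    # FP = 0 gives FDR 0
    expect_equal(calibrateFDR(10L, 0L, grid = 5.0)$table$FDR, 0)
})

test_that("the smallest admissible grid threshold is selected", {
    cal <- calibrateFDR(tp = c(100L, 90L, 80L), fp = c(10L, 3L, 1L),
                        grid = c(5, 5.5, 6), fdrMax = 0.04)
    expect_equal(cal$Z0, 5.5)      # 10/110 > 4% but 3/93 <= 4%
    expect_true(cal$ok)
    expect_warning(bad <- calibrateFDR(tp = c(10L, 10L), fp = c(5L, 4L),
                                       grid = c(5, 5.5), fdrMax = 0.04),
                   "largest")
    expect_equal(bad$Z0, 5.5)
    expect_false(bad$ok)
    # FDR is non-increasing along the grid for nested counts
    expect_true(all(diff(cal$table$FDR) <= 0))
})

test_that("overlap resolution keeps the best hit of each conflict group", {
    gr <- GenomicRanges::GRanges("c",
        IRanges::IRanges(c(1, 41, 200), width = 100),
        strand = "+")
    S4Vectors::mcols(gr)$Z <- c(6.1, 5.2, 5.0)
    S4Vectors::mcols(gr)$family <- c(1L, 2L, 3L)
    # hits 1-2 share 60 bases: keep Z = 6.1; hit 3 is unchallenged
    kept <- resolveOverlaps(gr, minShared = 50L)
    expect_equal(S4Vectors::mcols(kept)$Z, c(6.1, 5.0))

    # sharing exactly 50 bases is not an overlap (strictly more required)
    gr2 <- GenomicRanges::GRanges("c",
        IRanges::IRanges(c(1, 51), width = 100), strand = "+")
    S4Vectors::mcols(gr2)$Z <- c(6, 5)
    S4Vectors::mcols(gr2)$family <- c(1L, 2L)
    expect_equal(length(resolveOverlaps(gr2, 50L)), 2L)

    # different strand classes do not compete
    gr3 <- gr
    GenomicRanges::strand(gr3) <- c("+", "-", "+")
    expect_equal(length(resolveOverlaps(gr3, 50L)), 3L)

    # single hit unchanged
    expect_equal(length(resolveOverlaps(gr[1], 50L)), 1L)

    # after resolution no surviving same-strand pair shares > 50 bases
    set.seed(10)
    big <- GenomicRanges::GRanges("c",
        IRanges::IRanges(sample(1:2000, 60, TRUE), width = 120),
        strand = "+")
    S4Vectors::mcols(big)$Z <- runif(60, 5, 9)
    S4Vectors::mcols(big)$family <- sample(1:4, 60, TRUE)
    surv <- resolveOverlaps(big, 50L)
    ov <- GenomicRanges::findOverlaps(surv, minoverlap = 51L,
                                      drop.self = TRUE)
    expect_equal(length(ov), 0L)
})

test_that("searchFamily finds a planted copy and its reverse complement on opposite strands", {
    cfg <- microConfig()
    set.seed(14)
    mother <- sample(0:3, 60, TRUE)
    rc <- rev(bitwXor(mother, 1L))
    bg <- function(n) sample(0:3, n, TRUE)
    seqs <- c(bg(1500), mother, bg(1500), rc, bg(1500))
    g <- genomeIndexFromSequence(as.integer(seqs), names = "chr1")
    p1 <- repeatIP:::.dinucBackground(baseFrequencies(g))
    tr <- list(s1 = mother, s2 = seq_along(mother))
    pwm <- transformPWM(standardizeCounts(accumulateMAT(rep(list(tr), 40L),
                                                        cfg$L)),
                        p1, cfg$R0sq, cfg$K0)
    fam <- new("RepeatFamily", id = 1L, pwm = pwm, Nmax = 40L, iMax = 9L,
               hits = GenomicRanges::GRanges(), Z0 = NA_real_,
               fdr = data.frame())
    res <- searchFamily(g, fam, cfg, shuffled = shuffleGenome(g, 3),
                        seed = 21)
    hits <- res$hits
    expect_gte(length(hits), 2L)
    plus <- hits[as.character(GenomicRanges::strand(hits)) == "+"]
    minus <- hits[as.character(GenomicRanges::strand(hits)) == "-"]
    expect_gte(length(plus), 1L)
    expect_gte(length(minus), 1L)
    # the direct hit covers the planted copy, the inverted hit its
    # reverse complement, both reported in forward coordinates
    copy1 <- IRanges::IRanges(1501, 1560)
    copy2 <- IRanges::IRanges(3061, 3120)
    expect_true(any(IRanges::overlapsAny(IRanges::ranges(plus), copy1,
                                         minoverlap = 30L)))
    expect_true(any(IRanges::overlapsAny(IRanges::ranges(minus), copy2,
                                         minoverlap = 30L)))
    # hits of the doubly-inverted matrix equal hits of the original
    res2 <- searchFamily(g, new("RepeatFamily", id = 1L,
                                pwm = invertPWM(invertPWM(pwm)),
                                Nmax = 40L, iMax = 9L,
                                hits = GenomicRanges::GRanges(),
                                Z0 = NA_real_, fdr = data.frame()),
                         cfg, shuffled = shuffleGenome(g, 3), seed = 21)
    expect_equal(GenomicRanges::start(res2$hits),
                 GenomicRanges::start(hits))
})

test_that("masked genomes yield no hits for claimed bases", {
    cfg <- microConfig()
    set.seed(15)
    mother <- sample(0:3, 60, TRUE)
    seqs <- c(sample(0:3, 1000, TRUE), mother, sample(0:3, 1000, TRUE))
    g <- genomeIndexFromSequence(as.integer(seqs), names = "chr1")
    p1 <- repeatIP:::.dinucBackground(baseFrequencies(g))
    tr <- list(s1 = mother, s2 = seq_along(mother))
    pwm <- transformPWM(standardizeCounts(accumulateMAT(rep(list(tr), 40L),
                                                        cfg$L)),
                        p1, cfg$R0sq, cfg$K0)
    gm <- applyMask(g, cbind(start = 1001L, end = 1060L))
    res <- searchFamily(gm, pwm, cfg, shuffled = shuffleGenome(g, 3),
                        respectMask = TRUE, seed = 4)
    expect_false(any(IRanges::overlapsAny(
        IRanges::ranges(res$hits), IRanges::IRanges(1001, 1060),
        minoverlap = 10L)))
})
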