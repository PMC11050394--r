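test_that("column deviations match direct arithmetic", {
    # one column all-a out of N = 10 at p = 0.25
    M4 <- matrix(0L, 4, 1, dimnames = list(c("a", "t", "c", "g"), NULL))
    M4[1, 1] <- 10L
    w <- columnDeviation(M4, p = rep(0.25, 4))
    expect_equal(unname(w[1, 1]), 7.5 / sqrt(1.875), tolerance = 1e-12)
    expect_equal(unname(w[2, 1]), -2.5 / sqrt(1.875), tolerance = 1e-12)

    # a column matching expectation exactly gives zero deviations
    M4b <- matrix(c(2.5, 2.5, 2.5, 2.5), 4, 1)
    expect_true(all(columnDeviation(M4b, p = rep(0.25, 4)) == 0))

    # degenerate p rows are zeroed
    M4c <- matrix(c(5, 5, 0, 0), 4, 1)
    w3 <- columnDeviation(M4c, p = c(0.5, 0.5, 0, 0))
    expect_true(all(w3[3:4, ] == 0))
})

test_that("column deviations have unit variance under a multinomial null", {
    set.seed(21)
    p <- c(0.3, 0.3, 0.2, 0.2)
    M4 <- matrix(stats::rmultinom(300, 1000, p), nrow = 4)
    w <- columnDeviation(M4, p = p)
    expect_lt(abs(stats::var(as.vector(w)) - 1), 0.2)
})

test_that("the conservation statistic follows its closed form", {
    expect_equal(columnStatistic(rep(0, 4)), -sqrt(5))
    expect_equal(columnStatistic(chi = 12.5), 5 - sqrt(5))
    # under the null, X is centred near 0
    set.seed(5)
    M4 <- matrix(stats::rmultinom(1000, 1000, rep(0.25, 4)), nrow = 4)
    X <- columnStatistic(columnDeviation(M4, p = rep(0.25, 4)))
    # each of the four deviations has unit variance, so E[chi] = 4 and the
    # statistic sits slightly above 0 under the null (about sqrt(7) - sqrt(5))
    expect_lt(abs(mean(X) - (sqrt(7) - sqrt(5))), 0.15)
    expect_lt(abs(sd(X) - 1), 0.25)
})

test_that("symbolic consensus uses a strict majority", {
    M4 <- matrix(c(6, 2, 1, 1,     # 6 > 5 -> a
                   5, 3, 1, 1,     # 5 is not > 5 -> -
                   0, 0, 0, 0),    # empty -> -
                 nrow = 4)
    expect_equal(symbolicConsensus(M4), "a--")
})

test_that("the count matrix honours the asterisk deletion convention", {
    # alignment fragment: columns 21-26 then a base opposite a column
    # deletion, columns 27-29, a column with no base, then 31-33:
    #   a t c c g g t a c c * c t g   (bases; '*' = deleted base)
    # against columns 21 22 23 24 25 26 * 27 28 29 30 31 32 33
    s1 <- c(codesOf("atccgg"), codesOf("t"), codesOf("acc"), NA,
            codesOf("ctg"))
    s2 <- c(21:26, NA, 27:29, 30L, 31:33)
    M4 <- matrix(0L, 4, 40, dimnames = list(c("a", "t", "c", "g"), NULL))
    ok <- !is.na(s1) & !is.na(s2)
    for (k in which(ok)) M4[s1[k] + 1L, s2[k]] <- M4[s1[k] + 1L, s2[k]] + 1L
    # positions: (a,21) (t,22) (c,23) (c,24) (g,25) (g,26) then the 't'
    # opposite '*' and column 30 opposite '*' contribute nothing
    expect_equal(sum(M4), 12L)
    expect_equal(unname(M4[1, 21]), 1L); expect_equal(unname(M4[2, 22]), 1L)
    expect_equal(unname(M4[3, 28]), 1L); expect_equal(unname(M4[4, 33]), 1L)
    expect_equal(sum(M4[, 30]), 0L)
})

test_that("buildCountMatrix re-aligns identical members into full columns", {
    cfg <- microConfig()
    pg <- microPlanted(seed = 9, x = 0)
    g <- pg@genome
    truth <- plantedTruth(pg)
    # family matrix from the mother's own perfect trace
    mother <- codesOf(pg@mothers[1])
    tr <- list(s1 = mother, s2 = seq_along(mother))
    MAT <- accumulateMAT(rep(list(tr), 50L), cfg$L)
    pwm <- transformPWM(standardizeCounts(MAT),
                        repeatIP:::.dinucBackground(baseFrequencies(g)),
                        cfg$R0sq, cfg$K0)
    hits <- truth[1:20]
    S4Vectors::mcols(hits)$wstart <-
        pmax(1L, GenomicRanges::start(hits) - 5L)
    cm <- buildCountMatrix(hits, g, cfg, pwm = pwm)
    expect_equal(cm$nAligned, 20L)
    prof <- consensusProfile(cm$M4)
    # consensus over populated columns reproduces the mother
    pop <- prof$Nj >= 15
    cons <- strsplit(prof$consensus, "")[[1]]
    mstr <- strsplit(pg@mothers[1], "")[[1]]
    agree <- mean(cons[pop] == mstr[pop])
    expect_gt(agree, 0.95)
    expect_gt(median(prof$X[pop]), 3)
})

test_that("feature intersection rules are strict at 50%", {
    hits <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 100))
    S4Vectors::mcols(hits)$family <- 1L
    # overlap exactly 50 = 50% of the repeat: no pair in repeat mode
    gene50 <- GenomicRanges::GRanges("c", IRanges::IRanges(51, 400))
    expect_equal(nrow(intersectFeatures(hits, gene50, mode = "repeat")), 0L)
    # gene mode admits the pair when >50% of the *feature* overlaps
    gene60 <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 60))
    expect_equal(nrow(intersectFeatures(hits, gene60, mode = "gene")), 1L)
    expect_equal(nrow(intersectFeatures(hits, gene60, mode = "repeat")), 1L)
    # disjoint
    far <- GenomicRanges::GRanges("c", IRanges::IRanges(500, 600))
    expect_equal(nrow(intersectFeatures(hits, far, mode = "gene")), 0L)
    # many-to-many is allowed
    genes <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 1), c(80, 90)))
    expect_equal(nrow(intersectFeatures(hits, genes, mode = "repeat")), 2L)
})

test_that("class-family enrichment standardizes against independent margins", {
    pairs <- data.frame(class = c("LTR", "LTR", "DNA", "LTR"),
                        family = c(1, 1, 2, 2))
    enr <- classFamilyEnrichment(pairs)
    V <- enr$V
    expect_equal(sum(V), 4)
    # hand arithmetic for cell (LTR, family 1): x=3, y=2, n=4, p=6/16
    p <- 3 * 2 / 16
    expect_equal(enr$Vprime["LTR", "1"],
                 (2 - 4 * p) / sqrt(4 * p * (1 - p)))
    # single class x single family is degenerate -> 0
    one <- classFamilyEnrichment(data.frame(class = "A", family = 1))
    expect_equal(one$Vprime[1, 1], 0)

    # independent multinomial margins rarely exceed |v'| > 3
    set.seed(6)
    exc <- replicate(200, {
        V <- matrix(stats::rmultinom(1, 500,
                rep(1 / 24, 24)), nrow = 4)
        mean(abs(standardizeCounts(V)) > 3)
    })
    expect_lt(mean(exc), 0.01)
})

test_that("length histogram summarises hit lengths", {
    hits <- GenomicRanges::GRanges("c",
        IRanges::IRanges(c(1, 200, 900), width = c(108, 600, 522)))
    h <- lengthHistogram(hits)
    expect_equal(h$min, 108)
    expect_equal(h$max, 600)
    expect_equal(h$mean, mean(c(108, 600, 522)))
    one <- lengthHistogram(GenomicRanges::GRanges("c", IRanges::IRanges(1, 50)))
    expect_equal(one$mean, 50)
    empty <- lengthHistogram(GenomicRanges::GRanges())
    expect_equal(nrow(empty$table), 0L)
})
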