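p1unif <- rep(1 / 16, 16)

test_that("randomPWM draws uniform weights, deterministically under a seed", {
    m <- randomPWM(600L, seed = 3)
    expect_true(all(m >= -10 & m <= 10))
    expect_lt(abs(mean(m)), 0.3)           # uniform(-10,10) mean
    expect_identical(m, randomPWM(600L, seed = 3))
    expect_false(identical(m, randomPWM(600L, seed = 4)))
})

test_that("transformPWM enforces the weighted mean and norm constraints", {
    for (seed in 1:20) {
        m <- randomPWM(600L, seed = seed)
        pwm <- transformPWM(m, p1unif, 300 * sqrt(600), -1)
        expect_lt(abs(pwmWeightedMean(pwm) - (-1)), 1e-9)
        expect_lt(abs(pwmNormSq(pwm) - 300 * sqrt(600)),
                  1e-6 * 300 * sqrt(600))
    }
    # skewed background
    f <- c(a = .1, t = .2, c = .3, g = .4)
    p1 <- as.vector(outer(f, f))
    pwm <- transformPWM(randomPWM(50L, seed = 1), p1, 300 * sqrt(50), -1)
    expect_lt(abs(pwmWeightedMean(pwm) + 1), 1e-9)
    expect_lt(abs(pwmNormSq(pwm) - 300 * sqrt(50)), 1e-6 * 300 * sqrt(50))
})

test_that("transformPWM is idempotent and fixes satisfying matrices", {
    pwm <- transformPWM(randomPWM(120L, seed = 9), p1unif,
                        300 * sqrt(120), -1)
    again <- transformPWM(pwmWeights(pwm), p1unif, 300 * sqrt(120), -1)
    expect_lt(max(abs(pwmWeights(again) - pwmWeights(pwm))), 1e-9)
})

test_that("transformPWM matches an independent numeric solve on a toy matrix", {
    set.seed(2)
    m <- matrix(rnorm(32), nrow = 16, ncol = 2)
    L <- 2L; R0sq <- 300 * sqrt(L); K0 <- -1
    pwm <- transformPWM(m, p1unif, R0sq, K0)
    # oracle: solve for alpha numerically from the norm condition of the
    # affine family alpha*(m - Kbar) + K0
    wts <- outer(p1unif, rep(1 / L, L))
    Kbar <- sum(m * wts)
    normOf <- function(alpha) {
        w <- alpha * (m - Kbar) + K0
        L * sum(w^2 * wts) - R0sq
    }
    alphaHat <- uniroot(normOf, c(1e-8, 1e4), tol = 1e-12)$root
    expect_equal(pwmWeights(pwm),
                 alphaHat * (m - Kbar) + K0, tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("transformPWM rejects degenerate input", {
    expect_error(transformPWM(matrix(5, 16, 10), p1unif, 300 * sqrt(10)),
                 "degenerate")
})

test_that("invertPWM is an involution with the complement row mapping", {
    pwm <- transformPWM(randomPWM(30L, seed = 5), p1unif, 300 * sqrt(30), -1)
    inv <- invertPWM(pwm)
    back <- invertPWM(inv)
    expect_equal(pwmWeights(back), pwmWeights(pwm))
    expect_equal(pwmBackground(back), pwmBackground(pwm))
    # row 'at' (n = 5) is its own reverse complement
    expect_equal(pwmWeights(inv)["at", ], rev(pwmWeights(pwm)["at", ]))
    # rows 'aa' (n = 1) and 'tt' (n = 6) swap
    expect_equal(pwmWeights(inv)["tt", ], rev(pwmWeights(pwm)["aa", ]))
    expect_equal(pwmWeights(inv)["aa", ], rev(pwmWeights(pwm)["tt", ]))
    # p1 mass conserved
    expect_equal(sum(pwmBackground(inv)), 1)
})

test_that("inverted matrix scores the reverse complement like the original", {
    pwm <- transformPWM(randomPWM(20L, seed = 12), p1unif, 300 * sqrt(20), -1)
    s <- codesOf("acggttacgatcgtagcatgcatgca")
    rc <- rev(bitwXor(s, 1L))
    f1 <- alignProfile(pwm, s, 2, trace = FALSE)$score
    f2 <- alignProfile(invertPWM(pwm), rc, 2, trace = FALSE)$score
    expect_equal(f1, f2, tolerance = 1e-5)
})

test_that("accumulateMAT applies the deletion and first-position skip rules", {
    # perfect 3-base trace: only positions 2 and 3 count
    tr <- list(s1 = codesOf("acg"), s2 = 1:3)
    MAT <- accumulateMAT(list(tr), 3L)
    expect_equal(sum(MAT), 2L)
    expect_equal(unname(MAT[dinucleotideRow("a", "c"), 2]), 1L)
    expect_equal(unname(MAT[dinucleotideRow("c", "g"), 3]), 1L)

    # deletion in s1 voids itself and its successor
    tr2 <- list(s1 = c(0L, NA, 2L, 3L), s2 = c(1L, 2L, 3L, 4L))
    MAT2 <- accumulateMAT(list(tr2), 4L)
    expect_equal(sum(MAT2), 1L)
    expect_equal(unname(MAT2[dinucleotideRow("c", "g"), 4]), 1L)

    # column deletion voids only that position
    tr3 <- list(s1 = c(0L, 1L, 2L), s2 = c(1L, NA, 3L))
    MAT3 <- accumulateMAT(list(tr3), 3L)
    expect_equal(sum(MAT3), 1L)
    expect_equal(unname(MAT3[dinucleotideRow("t", "c"), 3]), 1L)

    expect_equal(sum(accumulateMAT(list(), 5L)), 0L)
    expect_error(accumulateMAT(list(list(s1 = c(0L, 1L), s2 = c(1L, 9L))), 3L),
                 "column")
})

test_that("standardizeCounts matches hand arithmetic and handles edge cases", {
    V <- matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE)
    # margins 4/4, N = 8, p = 0.25 each cell
    M <- standardizeCounts(V, scale = "deviate")
    expect_equal(M[1, 1], (3 - 2) / sqrt(8 * 0.25 * 0.75))
    expect_equal(M[1, 2], (1 - 2) / sqrt(8 * 0.25 * 0.75))
    # ratio scale: observed/expected departure without the square root
    R <- standardizeCounts(V)
    expect_equal(R[1, 1], (3 - 2) / (8 * 0.25 * 0.75))
    expect_equal(R[2, 1], (1 - 2) / (8 * 0.25 * 0.75))

    expect_true(all(standardizeCounts(matrix(7L, 4, 6)) == 0))
    expect_error(standardizeCounts(matrix(0L, 4, 4)), "empty")
    # single-cell degenerate margin: p = 1
    expect_equal(standardizeCounts(matrix(5, 1, 1))[1, 1], 0)
})

test_that("standardizeCounts is approximately standard normal under its null", {
    set.seed(31)
    vals <- replicate(200, {
        rowp <- rep(1 / 16, 16)
        colp <- rep(1 / 25, 25)
        V <- matrix(stats::rmultinom(1, 1e4, as.vector(outer(rowp, colp))),
                    16, 25)
        M <- standardizeCounts(V, scale = "deviate")
        c(mean(M), stats::var(as.vector(M)))
    })
    expect_lt(abs(mean(vals[1, ])), 0.05)
    expect_lt(abs(mean(vals[2, ]) - 1), 0.15)
})

test_that("PWM text serialization round-trips", {
    pwm <- transformPWM(randomPWM(25L, seed = 8), p1unif, 300 * sqrt(25), -1)
    path <- tempfile(fileext = ".pwm")
    writePWM(pwm, path)
    back <- readPWM(path)
    expect_equal(pwmWeights(back), pwmWeights(pwm), tolerance = 1e-12)
    expect_equal(pwmBackground(back), pwmBackground(pwm))
    expect_true(back@transformed)
})
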