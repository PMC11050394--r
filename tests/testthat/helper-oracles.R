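# Shared fixtures and independent oracles for the test suite.

# base codes: a=0, t=1, c=2, g=3, N=4
codesOf <- function(s) {
    map <- c(a = 0L, t = 1L, c = 2L, g = 3L, n = 4L)
    unname(map[strsplit(tolower(s), "")[[1]]])
}

# write a small FASTA file and return its path
tmpFasta <- function(seqs) {
    path <- tempfile(fileext = ".fa")
    writeLines(unlist(lapply(names(seqs), function(n)
        c(paste0(">", n), toupper(seqs[[n]])))), path)
    path
}

# random toy weight matrix
toyPWM <- function(L, sd = 2, mean = 0, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    matrix(rnorm(16 * L, mean, sd), nrow = 16)
}

# Exhaustive local-alignment oracle, independent of the DP implementation.
# Enumerates every sequence of matched pairs (i1<...<ik, j1<...<jk); the
# score of a trace is the sum of dinucleotide match weights (context =
# window-adjacent previous base, neutral at window position 1 or at an N)
# minus gap * (number of skipped bases + skipped columns between
# consecutive matched pairs).  The empty alignment scores 0.
enumerateAlignments <- function(codes, W, gap) {
    len <- length(codes)
    L <- ncol(W)
    matchW <- function(i, j) {
        if (i < 2 || codes[i - 1] >= 4 || codes[i] >= 4) return(0)
        W[codes[i - 1] + 4 * codes[i] + 1, j]
    }
    best <- 0
    recurse <- function(i0, j0, acc) {
        # acc: score of pairs chosen so far ending exactly at (i0, j0)
        if (acc > best) best <<- acc
        if (i0 >= len || j0 >= L) return()
        for (i in (i0 + 1):len) for (j in (j0 + 1):L) {
            gapcost <- gap * ((i - i0 - 1) + (j - j0 - 1))
            recurse(i, j, acc + matchW(i, j) - gapcost)
        }
    }
    for (i in seq_len(len)) for (j in seq_len(L))
        recurse(i, j, matchW(i, j))
    best
}

# micro-scale configuration for fast pipeline tests
microConfig <- function(...) {
    base <- list(L = 60L, window = 70L, step = 5L, halfwidth = 25L,
                 nIterations = 6L, nMatrices = 2L, iMin = 2L, Nmin = 20L,
                 nullWindows = 400L)
    do.call(ipConfig, utils::modifyList(base, list(...)))
}

# small planted genome with near-exact copies (micro pipeline scale)
microPlanted <- function(seed = 5, x = 0.2, nCopies = 120L) {
    makePlantedGenome(length = 20000, repeatLength = 60L,
                      nCopies = nCopies, x = x, seed = seed, minGap = 80L)
}
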