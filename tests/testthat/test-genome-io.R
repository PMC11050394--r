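test_that("loadGenome concatenates records in file order and computes composition", {
    fa <- tmpFasta(list(chrA = "ACGT"))
    g <- loadGenome(fa)
    expect_equal(genomeLength(g), 4L)
    expect_equal(unname(baseFrequencies(g)), rep(0.25, 4))

    fa2 <- tmpFasta(list(r1 = paste(rep("A", 10), collapse = ""),
                         r2 = paste(rep("G", 5), collapse = "")))
    g2 <- loadGenome(fa2)
    expect_equal(genomeLength(g2), 15L)
    expect_equal(genomeRecords(g2)$offset, c(0L, 10L))
    expect_equal(sum(baseFrequencies(g2)), 1)

    # non-ACGT characters become N and are excluded from composition
    fa3 <- tmpFasta(list(x = "ACGTNNRY"))
    g3 <- loadGenome(fa3)
    expect_equal(sum(genomeSequence(g3) == 4L), 4L)
    expect_equal(sum(baseFrequencies(g3)), 1)

    expect_error(loadGenome(tmpFasta(list(a = "ACGT", a = "ACGT"))),
                 "duplicate")
})

test_that("coordinate round-trips are exact across record boundaries", {
    g <- genomeIndexFromSequence(c(r1 = "acgtacgtac", r2 = "ggccg"))
    pos <- 1:15
    loc <- concatToRecord(g, pos)
    back <- recordToConcat(g, loc$record, loc$pos)
    expect_identical(back, as.integer(pos))
    expect_equal(loc$record, rep(c("r1", "r2"), c(10, 5)))
    expect_error(recordToConcat(g, "r2", 6))
    expect_error(concatToRecord(g, 16))
})

test_that("shuffleGenome preserves the base multiset and is seed-deterministic", {
    g <- genomeIndexFromSequence(c(x = "aaccggttnn"))
    s1 <- shuffleGenome(g, seed = 7)
    s2 <- shuffleGenome(g, seed = 7)
    s3 <- shuffleGenome(g, seed = 8)
    expect_identical(s1@seq, s2@seq)
    expect_false(identical(s1@seq, s3@seq))
    expect_equal(tabulate(s1@seq + 1L, 5), tabulate(g@seq + 1L, 5))
    # single base is trivially fixed
    expect_identical(shuffleGenome(genomeIndexFromSequence(c(o = "a")), 1)@seq,
                     genomeIndexFromSequence(c(o = "a"))@seq)
})

test_that("applyMask is cumulative, idempotent and bounds-checked", {
    g <- genomeIndexFromSequence(c(x = paste(rep("acgt", 10), collapse = "")))
    m1 <- applyMask(g, cbind(start = 1L, end = 10L))
    expect_equal(maskedBases(m1), 10L)
    expect_identical(genomeMask(applyMask(m1, cbind(1L, 10L))),
                     genomeMask(m1))
    m2 <- applyMask(g, cbind(start = c(1L, 4L), end = c(5L, 8L)))
    expect_equal(maskedBases(m2), 8L)
    expect_identical(applyMask(g, matrix(integer(0), ncol = 2)), g)
    expect_error(applyMask(g, cbind(0L, 5L)), "range")
    expect_error(applyMask(g, cbind(39L, 41L)), "range")
})

test_that("repeat tables round-trip through CSV and convert to BED", {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1L, 601L), c(600L, 750L)),
                                 strand = c("+", "-"))
    S4Vectors::mcols(gr)$family <- c(1L, 2L)
    S4Vectors::mcols(gr)$Z <- c(6.5, 5.1)
    csv <- tempfile(fileext = ".csv")
    writeRepeatTable(gr, csv)
    rt <- readRepeatTable(csv)
    expect_equal(GenomicRanges::start(rt), GenomicRanges::start(gr))
    expect_equal(GenomicRanges::end(rt), GenomicRanges::end(gr))
    expect_equal(S4Vectors::mcols(rt)$Z, S4Vectors::mcols(gr)$Z)
    expect_equal(as.character(GenomicRanges::strand(rt)),
                 as.character(GenomicRanges::strand(gr)))

    bed <- tempfile(fileext = ".bed")
    writeRepeatBed(gr, bed)
    b <- read.table(bed, sep = "\t")
    expect_equal(b$V2, c(0L, 600L))   # BED is 0-based half-open
    expect_equal(b$V3, c(600L, 750L))
})

test_that("GFF3 gene reader returns gene intervals and skips malformed lines", {
    gff <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 paste("chr1", "src", "gene", "100", "500", ".", "+", ".",
                       "ID=g1", sep = "\t"),
                 paste("chr1", "src", "mRNA", "100", "500", ".", "+", ".",
                       "ID=t1;Parent=g1", sep = "\t"),
                 paste("chr1", "src", "gene", "800", "1200", ".", "-", ".",
                       "ID=g2", sep = "\t"),
                 "chr1\tbroken line without enough fields",
                 paste("chr2", "src", "gene", "10", "90", ".", "+", ".",
                       "ID=g3", sep = "\t")), gff)
    expect_warning(genes <- readGeneAnnotations(gff), "malformed")
    expect_equal(length(genes), 3L)
    expect_equal(GenomicRanges::start(genes), c(100L, 800L, 10L))
})

test_that("annotated-repeat reader returns classed intervals", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("class\tchrom\tstart\tend",
                 "LTR/Copia\tchr1\t100\t400",
                 "DNA\tchr1\t900\t950"), tsv)
    adr <- readRepeatAnnotations(tsv)
    expect_equal(length(adr), 2L)
    expect_equal(S4Vectors::mcols(adr)$class, c("LTR/Copia", "DNA"))
    bad <- tempfile(fileext = ".tsv")
    writeLines("a\tb\n1\t2", bad)
    expect_error(readRepeatAnnotations(bad), "columns")
})

test_that("FASTA writer round-trips a genome", {
    g <- genomeIndexFromSequence(c(r1 = "acgtacgtnn", r2 = "ggcc"))
    fa <- tempfile(fileext = ".fa")
    writeGenomeFasta(g, fa)
    g2 <- loadGenome(fa)
    expect_identical(g2@seq, g@seq)
    expect_equal(genomeRecords(g2)$name, c("r1", "r2"))
})
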