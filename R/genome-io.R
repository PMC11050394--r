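# Encoding: a=0, t=1, c=2, g=3, anything else = 4 (N).
.ENCODE_TABLE <- local({
    tab <- rep(4L, 256L)
    tab[utf8ToInt("A") + 1L] <- 0L; tab[utf8ToInt("a") + 1L] <- 0L
    tab[utf8ToInt("T") + 1L] <- 1L; tab[utf8ToInt("t") + 1L] <- 1L
    tab[utf8ToInt("C") + 1L] <- 2L; tab[utf8ToInt("c") + 1L] <- 2L
    tab[utf8ToInt("G") + 1L] <- 3L; tab[utf8ToInt("g") + 1L] <- 3L
    tab
})

.encodeDNA <- function(x) {
    if (is(x, "XStringSet") || is(x, "XString")) x <- as.character(x)
    stopifnot(is.character(x), length(x) == 1L)
    .ENCODE_TABLE[as.integer(charToRaw(x)) + 1L]
}

.decodeDNA <- function(codes) {
    chars <- c("a", "t", "c", "g", "n")
    paste(chars[codes + 1L], collapse = "")
}

.baseFreqFromCodes <- function(codes) {
    tab <- tabulate(codes[codes < 4L] + 1L, nbins = 4L)
    if (sum(tab) == 0) return(setNames(rep(0.25, 4), .BASES))
    setNames(tab / sum(tab), .BASES)
}

#' Build a GenomeIndex from base codes or sequence strings
#'
#' @param seqs named character vector (or \code{DNAStringSet}) of record
#'   sequences, or a single integer vector of base codes.
#' @param names record names when \code{seqs} is a code vector.
#' @return a \code{\link{GenomeIndex}}.
#' @export
genomeIndexFromSequence <- function(seqs, names = NULL) {
    if (is.integer(seqs) || is.numeric(seqs)) {
        codes <- as.integer(seqs)
        nm <- if (is.null(names)) "seq1" else names
        recs <- data.frame(name = nm, length = length(codes), offset = 0L,
                           stringsAsFactors = FALSE)
    } else {
        if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
        if (is.null(names(seqs)))
            names(seqs) <- paste0("seq", seq_along(seqs))
        codes <- unlist(lapply(seqs, .encodeDNA), use.names = FALSE)
        lens <- nchar(seqs)
        recs <- data.frame(name = names(seqs), length = as.integer(lens),
                           offset = c(0L, cumsum(as.integer(lens))[-length(lens)]),
                           stringsAsFactors = FALSE)
    }
    new("GenomeIndex", seq = codes, records = recs,
        baseFreq = .baseFreqFromCodes(codes),
        mask = rep(FALSE, length(codes)))
}

#' Load a genome from a FASTA file
#'
#' Records are concatenated in file order into the single working sequence;
#' non-ACGT characters become N.  Base frequencies are computed once over
#' all non-N positions of the whole genome.
#'
#' @param path FASTA file (may be multi-record).
#' @return a \code{\link{GenomeIndex}}.
#' @export
loadGenome <- function(path) {
    dna <- readDNAStringSet(path)
    if (length(dna) == 0L) stop("no sequence records in ", path)
    if (anyDuplicated(names(dna)))
        stop("duplicate record names in ", path)
    # first whitespace-delimited token of the FASTA header
    names(dna) <- vapply(strsplit(names(dna), "\\s+"), `[`, "", 1L)
    genomeIndexFromSequence(dna)
}

#' GenomeIndex accessors
#' @param g a \code{GenomeIndex}.
#' @return \code{genomeLength}: total concatenated length in bases;
#'   \code{genomeRecords}: data.frame of record name/length/offset;
#'   \code{genomeSequence}: integer base codes; \code{baseFrequencies}:
#'   named numeric(4); \code{genomeMask}: logical mask; \code{maskedBases}:
#'   number of masked bases.
#' @export
genomeLength <- function(g) length(g@seq)

#' @rdname genomeLength
#' @export
genomeRecords <- function(g) g@records

#' @rdname genomeLength
#' @export
genomeSequence <- function(g) g@seq

#' @rdname genomeLength
#' @export
baseFrequencies <- function(g) g@baseFreq

#' @rdname genomeLength
#' @export
genomeMask <- function(g) g@mask

#' @rdname genomeLength
#' @export
maskedBases <- function(g) sum(g@mask)

#' Coordinate conversions between the concatenation and records
#'
#' Positions are 1-based inclusive on both sides.
#'
#' @param g a \code{GenomeIndex}.
#' @param pos concatenated positions (for \code{concatToRecord}).
#' @param record record names (for \code{recordToConcat}).
#' @param recPos positions within records.
#' @return \code{concatToRecord}: data.frame (record, pos);
#'   \code{recordToConcat}: integer concatenated positions.
#' @export
concatToRecord <- function(g, pos) {
    stopifnot(all(pos >= 1L), all(pos <= genomeLength(g)))
    idx <- findInterval(pos, g@records$offset + 1L)
    data.frame(record = g@records$name[idx],
               pos = as.integer(pos - g@records$offset[idx]),
               stringsAsFactors = FALSE)
}

#' @rdname concatToRecord
#' @export
recordToConcat <- function(g, record, recPos) {
    i <- match(record, g@records$name)
    if (anyNA(i)) stop("unknown record name(s)")
    stopifnot(all(recPos >= 1L), all(recPos <= g@records$length[i]))
    as.integer(g@records$offset[i] + recPos)
}

#' Shuffle a genome
#'
#' Randomly permutes the whole concatenated sequence (Fisher-Yates via
#' \code{sample.int}), preserving the exact base multiset.  Used to build
#' the null genome for score calibration.  The mask is cleared.
#'
#' @param g a \code{GenomeIndex}.
#' @param seed optional integer seed for reproducibility.
#' @return a shuffled \code{GenomeIndex}.
#' @export
shuffleGenome <- function(g, seed = NULL) {
    perm <- .withSeed(seed, sample.int(genomeLength(g)))
    new("GenomeIndex", seq = g@seq[perm], records = g@records,
        baseFreq = g@baseFreq, mask = rep(FALSE, genomeLength(g)))
}

# Normalize an interval specification to concatenated (start, end) pairs.
.asConcatIntervals <- function(g, intervals) {
    if (is(intervals, "GRanges")) {
        s <- recordToConcat(g, as.character(seqnames(intervals)),
                            start(intervals))
        e <- s + width(intervals) - 1L
        return(cbind(start = s, end = e))
    }
    if (is.data.frame(intervals)) {
        if (all(c("record", "start", "end") %in% names(intervals))) {
            s <- recordToConcat(g, intervals$record, intervals$start)
            e <- s + (intervals$end - intervals$start)
            return(cbind(start = s, end = as.integer(e)))
        }
        intervals <- as.matrix(intervals[, c("start", "end")])
    }
    m <- matrix(as.integer(intervals), ncol = 2L)
    colnames(m) <- c("start", "end")
    m
}

#' Mask genome intervals
#'
#' Marks bases claimed by an accepted family so later discovery rounds
#' ignore them.  Masking is cumulative and idempotent.
#'
#' @param g a \code{GenomeIndex}.
#' @param intervals a \code{GRanges} in record coordinates, a data.frame
#'   with columns record/start/end, or a 2-column matrix of concatenated
#'   1-based inclusive (start, end) pairs.
#' @return the updated \code{GenomeIndex}.
#' @export
applyMask <- function(g, intervals) {
    iv <- .asConcatIntervals(g, intervals)
    if (nrow(iv) == 0L) return(g)
    if (any(iv[, 1L] < 1L) || any(iv[, 2L] > genomeLength(g)) ||
        any(iv[, 2L] < iv[, 1L]))
        stop("interval out of range")
    mask <- g@mask
    for (k in seq_len(nrow(iv)))
        mask[iv[k, 1L]:iv[k, 2L]] <- TRUE
    new("GenomeIndex", seq = g@seq, records = g@records,
        baseFreq = g@baseFreq, mask = mask)
}

#' Write and read repeat hit tables
#'
#' The CSV table has columns family, record, start, end, strand, Z,
#' length with 1-based inclusive coordinates; the BED6 export uses the
#' usual 0-based half-open convention (start - 1).
#'
#' @param hits a \code{GRanges} with metadata columns \code{family} and
#'   \code{Z}.
#' @param path output file.
#' @return \code{readRepeatTable} returns the hits as a \code{GRanges}.
#' @export
writeRepeatTable <- function(hits, path) {
    df <- data.frame(family = mcols(hits)$family,
                     record = as.character(seqnames(hits)),
                     start = start(hits), end = end(hits),
                     strand = as.character(strand(hits)),
                     Z = mcols(hits)$Z, length = width(hits))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeRepeatTable
#' @export
readRepeatTable <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    gr <- GRanges(df$record, IRanges(df$start, df$end), strand = df$strand)
    mcols(gr)$family <- df$family
    mcols(gr)$Z <- df$Z
    gr
}

#' @rdname writeRepeatTable
#' @export
writeRepeatBed <- function(hits, path) {
    df <- data.frame(chrom = as.character(seqnames(hits)),
                     start = start(hits) - 1L, end = end(hits),
                     name = paste0("family", mcols(hits)$family),
                     score = round(mcols(hits)$Z, 3),
                     strand = as.character(strand(hits)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Lines that are not comments and do not have the nine tab-separated GFF
#' fields are skipped with a warning giving their count; the remainder is
#' parsed with \pkg{rtracklayer}.
#'
#' @param path GFF3 file.
#' @param featureType feature type(s) to keep (default "gene").
#' @return a \code{GRanges} of gene intervals.
#' @export
readGeneAnnotations <- function(path, featureType = "gene") {
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(lines)
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- nf != 9L
    if (any(bad)) {
        warning(sum(bad), " malformed GFF line(s) skipped")
        keep <- rep(TRUE, length(lines))
        keep[which(body)[bad]] <- FALSE
        tmp <- tempfile(fileext = ".gff3")
        writeLines(lines[keep], tmp)
        on.exit(unlink(tmp))
        path <- tmp
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr[mcols(gr)$type %in% featureType]
}

#' Read an annotated-repeat table
#'
#' Expects columns class, chrom, start, end (comma- or tab-separated,
#' chosen by file extension), 1-based inclusive.
#'
#' @param path table file.
#' @return a \code{GRanges} with metadata column \code{class}.
#' @export
readRepeatAnnotations <- function(path) {
    df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
        read.csv(path, stringsAsFactors = FALSE)
    else utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("class", "chrom", "start", "end")
    if (!all(need %in% names(df)))
        stop("annotated-repeat table must have columns ",
             paste(need, collapse = ", "))
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    mcols(gr)$class <- df$class
    gr
}

#' Write a genome to FASTA
#' @param g a \code{GenomeIndex}.
#' @param path output FASTA path.
#' @export
writeGenomeFasta <- function(g, path) {
    recs <- g@records
    seqs <- vapply(seq_len(nrow(recs)), function(i) {
        idx <- (recs$offset[i] + 1L):(recs$offset[i] + recs$length[i])
        toupper(.decodeDNA(g@seq[idx]))
    }, character(1))
    dna <- DNAStringSet(setNames(seqs, recs$name))
    writeXStringSet(dna, path)
    invisible(path)
}
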