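Package: repeatIP
Title: Iterative PWM Discovery of Highly Diverged Dispersed Repeat Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: De novo discovery of families of highly diverged dispersed
    repeats (transposable-element relics and related elements) in genomic
    sequence.  The method iteratively refines a 16-row dinucleotide position
    weight matrix (PWM) by alternating profile-sequence local dynamic
    programming scans of the genome with re-estimation of the matrix from the
    statistically significant scan maxima, calibrating significance against a
    shuffled-genome null and controlling the false discovery rate.  Includes
    both-strand search with the reverse-complement matrix, per-family
    consensus and per-column conservation statistics, intersection of repeat
    calls with gene and repeat annotations, and a planted-repeat genome
    simulator for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, Transposon, Repeat
NeedsCompilation: yes
RoxygenNote: 7.3.3
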