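#' Run the full discovery pipeline
#'
#' Discovers repeat families, re-searches the genome with every accepted
#' matrix on both strands, calibrates each family's threshold Z0 against
#' the shuffled genome (FDR within \code{config$fdrMax}), and resolves
#' cross-family overlaps per strand class.
#'
#' @param genome a \code{GenomeIndex}.
#' @param config an \code{\link{ipConfig}}.
#' @param seed master seed.
#' @param outputDir optional directory; when given, the hit tables (CSV +
#'   BED), per-family PWMs, FDR tables and the run manifest are written
#'   there.
#' @param verbose print progress.
#' @return list with \code{families} (RepeatFamily list, Z0/fdr filled
#'   in), \code{hits} (final deduplicated GRanges across families) and
#'   \code{manifest}.
#' @export
runPipeline <- function(genome, config, seed = 1L, outputDir = NULL,
                        verbose = FALSE) {
    families <- discoverFamilies(genome, config, seed = seed,
                                 verbose = verbose)
    shuffled <- shuffleGenome(genome, seed = .childSeed(seed, 0L))
    allHits <- GRanges()
    for (k in seq_along(families)) {
        res <- searchFamily(genome, families[[k]], config,
                            shuffled = shuffled,
                            seed = .childSeed(seed, 500L + k))
        families[[k]]@Z0 <- res$Z0
        families[[k]]@fdr <- res$fdr
        if (length(res$hits))
            allHits <- suppressWarnings(c(allHits, res$hits))
        if (verbose)
            message(sprintf("family %d: %d hits at Z0 = %.1f", k,
                            length(res$hits), res$Z0))
    }
    hits <- resolveOverlaps(allHits)
    manifest <- list(package = "repeatIP",
                     version = as.character(utils::packageVersion("repeatIP")),
                     seed = seed,
                     config = config[setdiff(names(config), "fdrGrid")],
                     fdrGrid = config$fdrGrid,
                     nFamilies = length(families),
                     familySizes = vapply(families, familySize, 0L),
                     nHits = length(hits))
    if (!is.null(outputDir)) {
        dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
        for (str in c("+", "-")) {
            sel <- hits[as.character(strand(hits)) == str]
            tag <- if (str == "+") "dir" else "inv"
            if (length(sel))
                writeRepeatTable(sel, file.path(outputDir,
                    paste0("repeats_", tag, ".csv")))
        }
        if (length(hits))
            writeRepeatBed(hits, file.path(outputDir, "repeats.bed"))
        for (k in seq_along(families)) {
            writePWM(families[[k]]@pwm,
                     file.path(outputDir, sprintf("family%02d.pwm", k)))
            if (nrow(families[[k]]@fdr))
                utils::write.table(families[[k]]@fdr,
                    file.path(outputDir, sprintf("family%02d_fdr.tsv", k)),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        }
        writeRunManifest(manifest, file.path(outputDir, "manifest.json"))
    }
    list(families = families, hits = hits, manifest = manifest)
}

#' Write the run manifest
#'
#' @param manifest list of run metadata (config, seeds, counts).
#' @param path output JSON path.
#' @export
writeRunManifest <- function(manifest, path) {
    write_json(manifest, path, auto_unbox = TRUE, digits = NA,
               pretty = TRUE)
    invisible(path)
}
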