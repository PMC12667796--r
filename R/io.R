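## Plain-text interchange: FASTA regions, tab-delimited motif matrices,
## per-base contribution tracks, BED-style hits, seqlet-stats JSON and
## seed-stamped score tables.

#' Read / write region sequences as FASTA
#'
#' @param path FASTA file path.
#' @param sequences named character vector of A/C/G/T sequences.
#' @return `readFastaRegions` returns a named character vector.
#' @export
writeFastaRegions <- function(sequences, path) {
    x <- Biostrings::DNAStringSet(sequences)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' @rdname writeFastaRegions
#' @export
readFastaRegions <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(x), names(x))
}

#' Read / write a motif matrix as tab-delimited text
#'
#' Format: a `# <name>` header line followed by an L x 4 table with
#' columns A, C, G, T. Used for both CWMs (signed weights) and PWMs
#' (probabilities).
#'
#' @param x a [CWM-class] or [PWM-class].
#' @param path file path.
#' @param what `"CWM"` or `"PWM"` for the reader.
#' @return the reader returns a [CWM-class] or [PWM-class].
#' @export
writeMotifMatrix <- function(x, path) {
    stopifnot(is(x, "CWM") || is(x, "PWM"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", x@name), con)
    utils::write.table(format(x@matrix, digits = 10), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMotifMatrix
#' @export
readMotifMatrix <- function(path, what = c("CWM", "PWM")) {
    what <- match.arg(what)
    lines <- readLines(path)
    name <- sub("^#\\s*", "", lines[1])
    m <- as.matrix(utils::read.table(text = lines[-1], header = TRUE,
                                     sep = "\t"))
    if (what == "CWM") newCWM(name, m) else newPWM(name, m)
}

#' Read / write a contribution track as TSV
#'
#' Columns: `pos` (0-based), `base` and the four per-nucleotide actual
#' contribution values.
#'
#' @param track a [ContributionTrack-class].
#' @param path file path.
#' @param regionId region identifier for the reader (defaults to the
#'   file's `# region` header).
#' @return the reader returns a [ContributionTrack-class].
#' @export
writeContributionTrack <- function(track, path) {
    stopifnot(is(track, "ContributionTrack"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# region\t", track@regionId), con)
    df <- data.frame(pos = seq_len(nrow(track@matrix)) - 1L,
                     base = strsplit(track@sequence, "")[[1]],
                     track@matrix, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeContributionTrack
#' @export
readContributionTrack <- function(path, regionId = NULL) {
    lines <- readLines(path)
    if (is.null(regionId) && startsWith(lines[1], "# region"))
        regionId <- sub("^# region\\t?\\s*", "", lines[1])
    df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t",
                            colClasses = c(base = "character"))
    m <- as.matrix(df[, .BASES])
    newContributionTrack(regionId, m, paste(df$base, collapse = ""))
}

#' Write motif hits as extended BED
#'
#' BED6 (`region`, `start`, `end`, `motif`, `jaccard`, `strand`) plus
#' columns `jaccard_pctl`, `l1`, `ic_score`, `ic_pctl`.
#'
#' @param hits data.frame of hits from [cwmScan()].
#' @param path file path.
#' @return the reader returns the hits data.frame.
#' @export
writeHitsBed <- function(hits, path) {
    bed <- data.frame(chrom = hits$region, start = hits$start,
                      end = hits$end, name = hits$motif,
                      score = hits$jaccard, strand = hits$strand,
                      jaccard_pctl = hits$jaccard_pctl, l1 = hits$l1,
                      ic_score = hits$ic_score, ic_pctl = hits$ic_pctl)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeHitsBed
#' @export
readHitsBed <- function(path) {
    df <- utils::read.table(path, sep = "\t",
                            col.names = c("region", "start", "end", "motif",
                                          "jaccard", "strand",
                                          "jaccard_pctl", "l1",
                                          "ic_score", "ic_pctl"))
    df[, c("region", "start", "end", "strand", "motif", "jaccard",
           "jaccard_pctl", "l1", "ic_score", "ic_pctl")]
}

#' Read / write seqlet statistics as JSON
#'
#' @param stats a named list of [SeqletStats-class] (one per motif).
#' @param path file path.
#' @return the reader returns a named list of [SeqletStats-class].
#' @export
writeSeqletStatsJson <- function(stats, path) {
    obj <- lapply(stats, function(s)
        list(motif = s@motif, jaccard = s@jaccard, l1 = s@l1, ic = s@ic))
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' @rdname writeSeqletStatsJson
#' @export
readSeqletStatsJson <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- lapply(obj, function(s)
        newSeqletStats(as.character(s$motif[1]), s$jaccard, s$l1,
                       if (is.null(s$ic)) numeric() else s$ic))
    stats::setNames(out, vapply(out, function(s) s@motif, character(1)))
}

#' Write a score table as TSV with provenance headers
#'
#' Prepends `#` comment lines recording the package version, the seed
#' and the log base (natural) before the tab-separated table.
#'
#' @param df data.frame of scores.
#' @param path file path.
#' @param seed integer seed recorded in the header.
#' @return the reader returns the data.frame (headers dropped).
#' @export
writeScoresTsv <- function(df, path, seed = NA_integer_) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        paste0("# pioneerCoop version ",
               as.character(utils::packageVersion("pioneerCoop"))),
        paste0("# seed ", seed),
        "# log base: natural"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeScoresTsv
#' @export
readScoresTsv <- function(path) {
    lines <- readLines(path)
    utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                      sep = "\t")
}
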