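## Matched background generation: GC / CpG-ratio summaries, exact
## dinucleotide (Euler-path) shuffling, nearest-neighbour pool sampling.

#' GC content of a sequence
#' @param sequence A/C/G/T string.
#' @return fraction of G+C bases.
#' @export
gcContent <- function(sequence) {
    b <- strsplit(toupper(sequence), "")[[1]]
    mean(b %in% c("G", "C"))
}

#' Observed/expected CpG ratio of a sequence
#'
#' The expected per-base CpG density is `(GC/2)^2` (the probability of a
#' C followed by a G under independent bases at the observed GC content),
#' normalized to the region width: the ratio is the observed count of CG
#' dinucleotides divided by `width * (GC/2)^2`. Undefined (NA) when the
#' sequence has no G/C bases.
#'
#' @param sequence A/C/G/T string, length >= 2.
#' @return numeric ratio, or `NA` when GC content is zero.
#' @examples
#' cpgRatio("ACGT")  # 4
#' @export
cpgRatio <- function(sequence) {
    sequence <- toupper(sequence)
    w <- nchar(sequence)
    stopifnot(w >= 2L)
    gc <- gcContent(sequence)
    if (gc == 0) return(NA_real_)
    b <- strsplit(sequence, "")[[1]]
    obs <- sum(b[-w] == "C" & b[-1] == "G")
    obs / (w * (gc / 2)^2)
}

#' Table of the 16 dinucleotide counts of a sequence
#' @param sequence A/C/G/T string.
#' @return named integer vector of length 16 (AA, AC, ..., TT).
#' @export
dinucleotideCounts <- function(sequence) {
    b <- strsplit(toupper(sequence), "")[[1]]
    di <- paste0(b[-length(b)], b[-1])
    lv <- as.vector(outer(.BASES, .BASES, paste0))
    table(factor(di, levels = sort(lv)))
}

#' Exact dinucleotide shuffle (Euler-path shuffle)
#'
#' Randomly permutes a sequence while preserving all 16 dinucleotide
#' counts exactly, along with the first and last base, using the
#' Altschul-Erikson algorithm: the sequence is an Eulerian path on the
#' 4-vertex base multigraph; a random arborescence toward the terminal
#' base fixes each vertex's last outgoing edge, the remaining out-edges
#' are permuted, and the path is rewalked.
#'
#' @param sequence A/C/G/T string, length >= 2.
#' @return shuffled sequence with identical dinucleotide composition.
#' @examples
#' set.seed(1)
#' x <- dinucleotideShuffle("ACGTACGTTGCA")
#' identical(dinucleotideCounts(x), dinucleotideCounts("ACGTACGTTGCA"))
#' @export
dinucleotideShuffle <- function(sequence) {
    sequence <- toupper(sequence)
    n <- nchar(sequence)
    stopifnot(n >= 2L)
    b <- strsplit(sequence, "")[[1]]
    if (anyNA(match(b, .BASES))) stop("sequence must be over A/C/G/T")
    from <- b[-n]
    to <- b[-1]
    last <- b[n]
    verts <- unique(b)
    ## out-edge target lists per vertex
    edges <- split(to, factor(from, levels = verts))
    if (length(unique(b)) == 1L) return(sequence)

    ## pick, for each non-terminal vertex with out-edges, a random last
    ## edge such that the chosen edges form a tree rooted at `last`
    nonTerminal <- setdiff(names(Filter(length, edges)), last)
    repeat {
        lastEdge <- vapply(nonTerminal, function(v) {
            outs <- edges[[v]]
            outs[sample.int(length(outs), 1L)]
        }, character(1))
        ## connectivity check: every non-terminal vertex must reach `last`
        ok <- TRUE
        for (v in nonTerminal) {
            cur <- v
            seen <- character()
            while (cur != last) {
                if (cur %in% seen || !(cur %in% names(lastEdge))) { ok <- FALSE; break }
                seen <- c(seen, cur)
                cur <- lastEdge[[cur]]
            }
            if (!ok) break
        }
        if (ok) break
    }

    ## permute the remaining out-edges; append the reserved last edge
    shuffled <- lapply(stats::setNames(names(edges), names(edges)), function(v) {
        outs <- edges[[v]]
        if (v %in% names(lastEdge)) {
            drop <- match(lastEdge[[v]], outs)
            rest <- outs[-drop]
            c(rest[sample.int(length(rest))], lastEdge[[v]])
        } else {
            outs[sample.int(length(outs))]
        }
    })

    ## rewalk the Eulerian path
    res <- character(n)
    res[1] <- b[1]
    ptr <- stats::setNames(rep(1L, length(shuffled)), names(shuffled))
    cur <- b[1]
    for (i in seq(2L, n)) {
        nxt <- shuffled[[cur]][ptr[[cur]]]
        ptr[[cur]] <- ptr[[cur]] + 1L
        res[i] <- nxt
        cur <- nxt
    }
    paste(res, collapse = "")
}

#' Generate matched, dinucleotide-shuffled background sequences
#'
#' Emulates drawing in silico backgrounds from trained peak regions:
#' pool members closest to the target GC content and CpG ratio (Euclidean
#' distance after z-scaling both summaries over the pool) are sampled
#' without replacement (recycling when `n` exceeds the pool) and each is
#' dinucleotide-shuffled, which preserves its GC and CpG composition
#' exactly while destroying motifs.
#'
#' @param pool character vector of source sequences (non-empty).
#' @param n number of backgrounds (default 256).
#' @param gcTarget,cpgTarget matching targets; default to the pool means.
#' @param seed integer seed.
#' @return A [BackgroundSet-class].
#' @export
generateBackgrounds <- function(pool, n = 256L, gcTarget = NULL,
                                cpgTarget = NULL, seed = 1L) {
    if (!length(pool)) stop("background pool must be non-empty")
    stopifnot(n >= 1L)
    n <- as.integer(n)
    gc <- vapply(pool, gcContent, numeric(1), USE.NAMES = FALSE)
    cpg <- vapply(pool, cpgRatio, numeric(1), USE.NAMES = FALSE)
    cpg[is.na(cpg)] <- 0
    if (is.null(gcTarget)) gcTarget <- mean(gc)
    if (is.null(cpgTarget)) cpgTarget <- mean(cpg)
    zs <- function(x, target) {
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0) s <- 1
        (x - target) / s
    }
    dist <- sqrt(zs(gc, gcTarget)^2 + zs(cpg, cpgTarget)^2)
    ord <- order(dist)
    idx <- rep_len(ord[seq_len(min(n, length(pool)))], n)
    .withSeed(seed, {
        seqs <- vapply(pool[idx], dinucleotideShuffle, character(1),
                       USE.NAMES = FALSE)
        new("BackgroundSet", sequences = seqs,
            gcTarget = gcTarget, cpgTarget = cpgTarget,
            seed = as.integer(seed))
    })
}

#' Random A/C/G/T sequence at a target GC content
#'
#' @param width sequence length.
#' @param gc target GC fraction; G/C and A/T are drawn symmetrically.
#' @return character sequence.
#' @export
randomSequence <- function(width, gc = 0.5) {
    paste(sample(.BASES, width, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}
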