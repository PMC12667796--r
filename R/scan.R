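## CWM scanning of contribution tracks: continuous Jaccard similarity,
## sliding-window hit calling against seqlet-derived thresholds,
## redundancy/palindrome resolution, information-content PWM scoring.

#' Continuous Jaccard similarity of two signed matrices
#'
#' Sign-aware min/max form: `sum(s * pmin(|a|,|b|)) / sum(pmax(|a|,|b|))`
#' over all entries, where `s` is +1 when the signs agree and -1
#' otherwise. Ranges over \[-1, 1\]; 1 for identical matrices, -1 for a
#' matrix and its negation, 0 for disjoint supports. `NA` when both
#' matrices are all-zero.
#'
#' @param a,b numeric matrices of equal shape.
#' @return similarity in \[-1, 1\], or `NA`.
#' @export
continuousJaccard <- function(a, b) {
    stopifnot(identical(dim(a), dim(b)))
    den <- sum(pmax(abs(a), abs(b)))
    if (den == 0) return(NA_real_)
    s <- ifelse(a * b >= 0, 1, -1)
    sum(s * pmin(abs(a), abs(b))) / den
}

#' Reverse complement of a CWM / motif matrix
#'
#' Reverses the positions and swaps complementary columns (A<->T, C<->G)
#' with signs preserved.
#'
#' @param m L x 4 matrix with columns A, C, G, T (or a [CWM-class]).
#' @return matrix (or CWM) of the same shape.
#' @export
cwmReverseComplement <- function(m) {
    if (is(m, "CWM")) {
        return(newCWM(m@name, cwmReverseComplement(m@matrix), m@nSeqlets))
    }
    out <- m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L), drop = FALSE]
    colnames(out) <- .BASES
    out
}

#' Scan a contribution track with a CWM
#'
#' Slides the CWM over the track in both orientations and emits a hit
#' wherever (1) the continuous Jaccard similarity with the window's
#' actual contributions exceeds the 20th percentile of the motif's
#' seqlet Jaccard distribution, and (2) the window's L1 contribution
#' magnitude exceeds the minimum seqlet contribution. No PWM log-odds
#' requirement is applied, so degenerate sequences with well-positioned
#' contributions can be mapped. Following the CWM-scanning lineage, the
#' Jaccard comparison is made between L1-normalized matrices, so it
#' measures contribution shape while the L1 criterion measures
#' magnitude. The strand is the orientation with the higher Jaccard;
#' overlapping candidate windows for the same motif are reduced to the
#' strongest (greedy by Jaccard).
#'
#' @param track a [ContributionTrack-class].
#' @param cwm a [CWM-class]; must be shorter than the track.
#' @param stats the motif's [SeqletStats-class] (thresholds and
#'   percentile reference).
#' @param pwm optional [PWM-class] used to attach information-content
#'   scores and percentiles to hits.
#' @return data.frame of hits: `region`, `start`, `end` (0-based
#'   half-open), `strand`, `motif`, `jaccard`, `jaccard_pctl`, `l1`,
#'   `ic_score`, `ic_pctl`.
#' @export
cwmScan <- function(track, cwm, stats, pwm = NULL) {
    stopifnot(is(track, "ContributionTrack"), is(cwm, "CWM"),
              is(stats, "SeqletStats"))
    L <- nrow(cwm@matrix)
    W <- nrow(track@matrix)
    if (L > W) stop("CWM longer than the track")
    jThr <- jaccardThreshold(stats)
    l1Min <- l1Threshold(stats)
    norm1 <- function(m) m / max(sum(abs(m)), .Machine$double.eps)
    fwd <- norm1(cwm@matrix)
    rev <- cwmReverseComplement(fwd)
    tm <- track@matrix

    cand <- vector("list", W - L + 1L)
    for (s in seq_len(W - L + 1L)) {
        win <- tm[s:(s + L - 1L), , drop = FALSE]
        l1 <- sum(abs(win))
        if (l1 <= l1Min) next
        win <- win / l1
        jF <- continuousJaccard(fwd, win)
        jR <- continuousJaccard(rev, win)
        if (is.na(jF) || is.na(jR)) next
        j <- max(jF, jR)
        if (j <= jThr) next
        cand[[s]] <- data.frame(
            region = track@regionId, start = s - 1L, end = s - 1L + L,
            strand = if (jF >= jR) "+" else "-", motif = cwm@name,
            jaccard = j, l1 = l1)
    }
    hits <- do.call(rbind, cand)
    empty <- data.frame(region = character(), start = integer(),
                        end = integer(), strand = character(),
                        motif = character(), jaccard = numeric(),
                        jaccard_pctl = numeric(), l1 = numeric(),
                        ic_score = numeric(), ic_pctl = numeric())
    if (is.null(hits)) return(empty)

    ## greedy non-maximum suppression of overlapping windows
    hits <- hits[order(-hits$jaccard, hits$start), , drop = FALSE]
    keep <- logical(nrow(hits))
    for (i in seq_len(nrow(hits))) {
        ov <- keep & hits$start < hits$end[i] & hits$start[i] < hits$end
        if (!any(ov)) keep[i] <- TRUE
    }
    hits <- hits[keep, , drop = FALSE]
    hits <- hits[order(hits$start), , drop = FALSE]

    hits$jaccard_pctl <- vapply(hits$jaccard, percentileOf,
                                numeric(1), stats@jaccard)
    if (!is.null(pwm)) {
        seqs <- substring(track@sequence, hits$start + 1L, hits$end)
        hits$ic_score <- vapply(seq_along(seqs), function(i) {
            s <- seqs[i]
            if (hits$strand[i] == "-")
                s <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(s)))
            pwmIcScore(s, pwm)
        }, numeric(1))
        hits$ic_pctl <- if (length(stats@ic))
            vapply(hits$ic_score, percentileOf, numeric(1), stats@ic)
        else NA_real_
    } else {
        hits$ic_score <- NA_real_
        hits$ic_pctl <- NA_real_
    }
    rownames(hits) <- NULL
    hits[, names(empty)]
}

#' Resolve redundant and palindromic motif hits
#'
#' Two refinements after scanning: (1) same-motif hits on opposite
#' strands at the same locus (any overlap) keep the higher Jaccard (tie:
#' the + strand); (2) within each declared redundancy class (e.g. a
#' composite motif and its embedded submotif), overlapping hits keep the
#' larger L1 contribution magnitude, so the output is non-overlapping
#' within each class. Idempotent.
#'
#' @param hits data.frame of hits as from [cwmScan()] (any regions/motifs
#'   mixed).
#' @param redundancyMap list of character vectors, each naming the motifs
#'   of one redundancy class.
#' @param knownMotifs motif names considered valid; a redundancy class
#'   naming an unknown motif is a configuration error. Defaults to the
#'   motifs present in `hits` together with those in the map.
#' @return filtered hits data.frame.
#' @export
resolveOverlaps <- function(hits, redundancyMap = list(),
                            knownMotifs = NULL) {
    if (is.null(knownMotifs))
        knownMotifs <- union(unique(hits$motif), unlist(redundancyMap))
    unknown <- setdiff(unlist(redundancyMap), knownMotifs)
    if (length(unknown))
        stop("unknown motif name in redundancy map: ",
             paste(unknown, collapse = ", "))
    if (!nrow(hits)) return(hits)
    hits <- hits[order(hits$region, hits$start), , drop = FALSE]

    dropOverlapping <- function(h, rankCols) {
        ## greedy: best-ranked hit wins, overlapping rest dropped
        ord <- do.call(order, rankCols)
        h <- h[ord, , drop = FALSE]
        keep <- logical(nrow(h))
        for (i in seq_len(nrow(h))) {
            ov <- keep & h$region == h$region[i] &
                h$start < h$end[i] & h$start[i] < h$end
            if (!any(ov)) keep[i] <- TRUE
        }
        h[keep, , drop = FALSE]
    }

    ## palindromic duplicates: per motif, prefer jaccard then + strand
    resolved <- do.call(rbind, lapply(split(hits, hits$motif), function(h) {
        dropOverlapping(h, list(-h$jaccard, h$strand != "+", h$start))
    }))

    ## redundancy classes: larger L1 wins across motifs of a class
    for (cls in redundancyMap) {
        inCls <- resolved$motif %in% cls
        if (!any(inCls)) next
        h <- resolved[inCls, , drop = FALSE]
        h <- dropOverlapping(h, list(-h$l1, -h$jaccard, h$start))
        resolved <- rbind(resolved[!inCls, , drop = FALSE], h)
    }
    resolved <- resolved[order(resolved$region, resolved$start,
                               resolved$motif), , drop = FALSE]
    rownames(resolved) <- NULL
    resolved
}

#' Information-content PWM match score of a sequence
#'
#' Per-position information content `IC_i = 2 + sum_b p_i(b) log2 p_i(b)`
#' (bits); the default score weights each position's IC by the
#' probability of the observed base, `sum_i p_i(b_i) * IC_i`, so a
#' deterministic PWM scores 2L on its consensus and a uniform PWM scores
#' 0 on anything. `method = "match"` instead sums IC only over positions
#' where the observed base is the consensus base.
#'
#' @param sequence A/C/G/T string of the PWM's length.
#' @param pwm a [PWM-class].
#' @param method `"weighted"` (default) or `"match"`.
#' @return numeric score (bits).
#' @export
pwmIcScore <- function(sequence, pwm, method = c("weighted", "match")) {
    method <- match.arg(method)
    stopifnot(is(pwm, "PWM"))
    m <- pwm@matrix
    b <- match(strsplit(toupper(sequence), "")[[1]], .BASES)
    if (length(b) != nrow(m)) stop("sequence length must equal PWM length")
    if (anyNA(b)) stop("sequence must be over A/C/G/T")
    plogp <- m * log2(m)
    plogp[m == 0] <- 0
    ic <- 2 + rowSums(plogp)
    pObs <- m[cbind(seq_along(b), b)]
    switch(method,
        weighted = sum(pObs * ic),
        match = sum(ic[b == apply(m, 1L, which.max)]))
}

#' Percentile of a score within a reference distribution
#'
#' @param score numeric scalar.
#' @param values reference distribution (e.g. seqlet scores).
#' @return percentile in \[0, 100\].
#' @export
percentileOf <- function(score, values) {
    stopifnot(length(values) >= 1L)
    100 * mean(values <= score)
}
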