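## Predictor-based motif scoring: isolation (injection into backgrounds),
## context (in situ ablation), pairwise cooperativity (double-mutant
## scenarios) and the distance-binned cooperativity significance test.

## Replace [start, end) (0-based half-open) of a sequence with `repl`.
.spliceSeq <- function(sequence, start, end, repl) {
    paste0(substr(sequence, 1L, start), repl,
           substr(sequence, end + 1L, nchar(sequence)))
}

## Uniform random A/C/G/T replacement of the same width.
.randomReplacement <- function(width) {
    paste(sample(.BASES, width, replace = TRUE), collapse = "")
}

.checkSpan <- function(sequence, start, end) {
    if (start < 0 || end <= start || end > nchar(sequence))
        stop("coordinate error: span [", start, ", ", end,
             ") outside region of length ", nchar(sequence))
}

#' Isolation score of a motif sequence
#'
#' Injects the motif sequence into every background (replacing the
#' underlying bases, centered in the predictor's output window by
#' default), predicts log counts with and without the injection,
#' exponentiates, averages in counts space across the background set, and
#' returns the natural-log fold-change of injected over background means.
#' A proxy for intrinsic motif strength out of genomic context.
#'
#' @param predictor a [Predictor-class].
#' @param motifSequence A/C/G/T string shorter than the background width.
#' @param backgrounds a [BackgroundSet-class] or character vector.
#' @param offset injection offset (bp) from the window center.
#' @return numeric log-fold-change.
#' @export
isolationScore <- function(predictor, motifSequence, backgrounds,
                           offset = 0L) {
    seqs <- if (is(backgrounds, "BackgroundSet"))
        backgroundSequences(backgrounds) else as.character(backgrounds)
    stopifnot(length(seqs) >= 1L)
    W <- nchar(seqs[1])
    L <- nchar(motifSequence)
    if (L > W) stop("motif longer than the background window")
    start <- floor((W - L) / 2) + as.integer(offset)  # 0-based
    if (start < 0 || start + L > W)
        stop("injection offset places the motif outside the window")
    bg <- vapply(seqs, function(s) exp(predictLogCounts(predictor, s)),
                 numeric(1), USE.NAMES = FALSE)
    inj <- vapply(seqs, function(s) {
        exp(predictLogCounts(predictor, .spliceSeq(s, start, start + L,
                                                   motifSequence)))
    }, numeric(1), USE.NAMES = FALSE)
    log(mean(inj) / mean(bg))
}

#' Context score of a mapped motif
#'
#' Ablates the motif in situ: the span is replaced by uniform random
#' bases independently in each of `nTrials` trials, predictions are
#' exponentiated and averaged across trials, and the score is the
#' natural-log fold-change of the wildtype counts over the mean mutant
#' counts. Measures the motif's contribution within its genomic context,
#' including any cooperativity with neighbours.
#'
#' @param predictor a [Predictor-class].
#' @param sequence region sequence.
#' @param start,end motif span, 0-based half-open, within the region.
#' @param nTrials number of random-replacement trials (default 16).
#' @param region optional region identifier passed to the predictor.
#' @param seed optional integer seed for the replacement draws.
#' @return numeric log-fold-change.
#' @export
contextScore <- function(predictor, sequence, start, end, nTrials = 16L,
                         region = NULL, seed = NULL) {
    .checkSpan(sequence, start, end)
    .withSeed(seed, {
        wt <- exp(predictLogCounts(predictor, sequence, region))
        mut <- vapply(seq_len(nTrials), function(i) {
            s <- .spliceSeq(sequence, start, end, .randomReplacement(end - start))
            exp(predictLogCounts(predictor, s, region))
        }, numeric(1))
        log(wt / mean(mut))
    })
}

#' Pairwise cooperativity of two motifs in one region
#'
#' Evaluates the four sequence scenarios -- wildtype (AB), A only (B
#' ablated), B only (A ablated) and null (both ablated) -- each ablation
#' a uniform random replacement averaged over `nTrials` trials in
#' exponentiated-counts space. Joint effect: `e_AB - e_null`; marginal:
#' `(e_A - e_null) + (e_B - e_null)`; score: `log(joint / marginal)`,
#' flagged invalid (NA score) when either is non-positive. Positive
#' scores mean superadditivity.
#'
#' @param predictor a [Predictor-class].
#' @param sequence region sequence.
#' @param spanA,spanB numeric `c(start, end)` 0-based half-open spans;
#'   must not overlap.
#' @param nTrials replacement trials per mutated scenario (default 16).
#' @param paired reuse the same replacement draws for a motif across the
#'   single- and double-mutant scenarios (default independent draws).
#' @param region optional region identifier passed to the predictor.
#' @param seed optional integer seed.
#' @return one-row data.frame: `distance` (center-to-center, bp),
#'   `e_null`, `e_A`, `e_B`, `e_AB`, `joint`, `marginal`, `score`,
#'   `valid`.
#' @export
pairwiseCooperativity <- function(predictor, sequence, spanA, spanB,
                                  nTrials = 16L, paired = FALSE,
                                  region = NULL, seed = NULL) {
    .checkSpan(sequence, spanA[1], spanA[2])
    .checkSpan(sequence, spanB[1], spanB[2])
    if (spanA[1] < spanB[2] && spanB[1] < spanA[2])
        stop("motif spans must not overlap")
    wA <- spanA[2] - spanA[1]
    wB <- spanB[2] - spanB[1]
    .withSeed(seed, {
        eAB <- exp(predictLogCounts(predictor, sequence, region))
        replA <- replicate(nTrials, .randomReplacement(wA))
        replB <- replicate(nTrials, .randomReplacement(wB))
        replA2 <- if (paired) replA else replicate(nTrials, .randomReplacement(wA))
        replB2 <- if (paired) replB else replicate(nTrials, .randomReplacement(wB))
        meanCounts <- function(rA, rB) {
            mean(vapply(seq_len(nTrials), function(i) {
                s <- sequence
                if (!is.null(rA)) s <- .spliceSeq(s, spanA[1], spanA[2], rA[i])
                if (!is.null(rB)) s <- .spliceSeq(s, spanB[1], spanB[2], rB[i])
                exp(predictLogCounts(predictor, s, region))
            }, numeric(1)))
        }
        eA <- meanCounts(NULL, replB)      # B ablated, A intact
        eB <- meanCounts(replA, NULL)      # A ablated, B intact
        eNull <- meanCounts(replA2, replB2)
        joint <- eAB - eNull
        marginal <- (eA - eNull) + (eB - eNull)
        valid <- joint > 0 && marginal > 0
        data.frame(
            distance = abs((spanA[1] + spanA[2]) / 2 - (spanB[1] + spanB[2]) / 2),
            e_null = eNull, e_A = eA, e_B = eB, e_AB = eAB,
            joint = joint, marginal = marginal,
            score = if (valid) log(joint / marginal) else NA_real_,
            valid = valid)
    })
}

#' Distance-binned cooperativity significance test
#'
#' Splits valid cooperativity records into distance bins (default 10 bp)
#' and tests each bin against the far reference group (records beyond
#' `farThreshold`, default 400 bp, deemed too distant for cooperative
#' pioneering) with a one-tailed Wilcoxon rank-sum test (alternative:
#' bin scores greater), Bonferroni-corrected over the bins actually
#' tested. Bins with fewer than `minPairs` records are excluded.
#'
#' @param records data.frame with columns `distance`, `score` and
#'   optionally `valid` (e.g. rows from [pairwiseCooperativity()]).
#' @param binWidth bin width in bp.
#' @param farThreshold far-group distance cutoff in bp.
#' @param minPairs minimum records per tested bin.
#' @param alpha adjusted significance cutoff (default 1e-7).
#' @return data.frame with one row per tested bin: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `n`, `median_score`, `p`, `p_adj`, `significant`.
#'   Attributes `n_far` and `n_invalid` report the reference-group size
#'   and the number of excluded invalid records.
#' @export
binnedCooperativityTest <- function(records, binWidth = 10, farThreshold = 400,
                                    minPairs = 20L, alpha = 1e-7) {
    stopifnot(all(c("distance", "score") %in% names(records)))
    nInvalid <- 0L
    if ("valid" %in% names(records)) {
        nInvalid <- sum(!records$valid | is.na(records$score))
        records <- records[records$valid & !is.na(records$score), , drop = FALSE]
    } else {
        nInvalid <- sum(is.na(records$score))
        records <- records[!is.na(records$score), , drop = FALSE]
    }
    far <- records$score[records$distance > farThreshold]
    if (!length(far)) stop("reference-group error: no records beyond farThreshold")
    lo <- seq(0, farThreshold - binWidth, by = binWidth)
    rows <- lapply(lo, function(l) {
        sc <- records$score[records$distance >= l & records$distance < l + binWidth]
        if (length(sc) < minPairs) return(NULL)
        p <- stats::wilcox.test(sc, far, alternative = "greater",
                                exact = FALSE, correct = TRUE)$p.value
        data.frame(bin_lo = l, bin_hi = l + binWidth, bin_mid = l + binWidth / 2,
                   n = length(sc), median_score = stats::median(sc), p = p)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) {
        rows <- data.frame(bin_lo = numeric(), bin_hi = numeric(),
                           bin_mid = numeric(), n = integer(),
                           median_score = numeric(), p = numeric(),
                           p_adj = numeric(), significant = logical())
    } else {
        rows$p_adj <- pmin(1, rows$p * nrow(rows))
        rows$significant <- rows$p_adj < alpha
    }
    attr(rows, "n_far") <- length(far)
    attr(rows, "n_invalid") <- nInvalid
    rows
}

#' Distance to the strongest pioneer motif of each region
#'
#' For every motif, the center-to-center distance (bp) to the motif with
#' the highest context score in the same region (ties broken by smallest
#' start coordinate). The strongest motif itself receives `NA` so it can
#' be excluded downstream.
#'
#' @param spans data.frame with columns `region`, `start`, `end` (0-based
#'   half-open) and `contextScore`.
#' @return the input with a `distanceToStrongest` column appended.
#' @export
distanceToStrongestPioneer <- function(spans) {
    stopifnot(all(c("region", "start", "end", "contextScore") %in% names(spans)))
    spans$distanceToStrongest <- NA_real_
    for (r in unique(spans$region)) {
        i <- which(spans$region == r)
        sub <- spans[i, ]
        best <- i[order(-sub$contextScore, sub$start)[1]]
        centers <- (spans$start[i] + spans$end[i]) / 2
        bestCenter <- (spans$start[best] + spans$end[best]) / 2
        d <- abs(centers - bestCenter)
        d[i == best] <- NA_real_
        spans$distanceToStrongest[i] <- d
    }
    spans
}
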