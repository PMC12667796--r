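## Shared fixtures: all built in code at test time.

## Partner parameter set sharing the conformational rates of `a`
## (one nucleosome per locus: kOpen and d are locus properties).
sharedLocus <- function(a, b) {
    b@kOpen <- a@kOpen
    b@d <- a@d
    b
}

## Independent steady-state oracle: stiff time integration of the master
## equation dp/dt = Q p from the uniform distribution to t = 1e6 / min
## positive rate.
odeSteadyState <- function(rm) {
    Q <- rateMatrix(rm)
    rmin <- min(Q[Q > 0])
    out <- deSolve::lsoda(
        rep(1 / nrow(Q), nrow(Q)), c(0, 1e6 / rmin),
        function(t, y, parms) list(Q %*% y), NULL,
        rtol = 1e-10, atol = 1e-12)
    unname(out[2, -1])
}

## Scan every track of a synthetic contribution set with every motif,
## resolve overlaps, and report recall/precision against planted truth
## (a hit is true when it overlaps a planted span of the same motif).
scanRecallPrecision <- function(sim, sc) {
    hits <- list()
    for (id in names(sc$tracks)) {
        for (nm in names(sc$stats)) {
            h <- cwmScan(sc$tracks[[id]], sc$cwms[[nm]], sc$stats[[nm]])
            if (nrow(h)) hits[[length(hits) + 1L]] <- h
        }
    }
    hits <- resolveOverlaps(do.call(rbind, hits))
    truth <- sim$truth$motifs[sim$truth$motifs$effect > 0, ]
    tp <- sum(vapply(seq_len(nrow(truth)), function(i) any(
        hits$region == truth$region[i] & hits$motif == truth$motif[i] &
        hits$start < truth$end[i] & truth$start[i] < hits$end),
        logical(1)))
    fp <- sum(vapply(seq_len(nrow(hits)), function(j) !any(
        truth$region == hits$region[j] & truth$motif == hits$motif[j] &
        truth$start < hits$end[j] & hits$start[j] < truth$end),
        logical(1)))
    list(recall = tp / nrow(truth),
         precision = (nrow(hits) - fp) / nrow(hits),
         hits = hits, truth = truth)
}

## Reverse complement of a plain character sequence.
rcSeq <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
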