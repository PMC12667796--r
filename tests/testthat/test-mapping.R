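## CWM scanning, Jaccard similarity, overlap resolution and IC scoring.

test_that("continuous Jaccard has the identity, negation and disjoint limits", {
    set.seed(2)
    m <- matrix(stats::rnorm(36), 9, 4)
    expect_equal(continuousJaccard(m, m), 1)
    expect_equal(continuousJaccard(m, -m), -1)
    a <- matrix(0, 9, 4); a[, 1] <- 1
    b <- matrix(0, 9, 4); b[, 2] <- 1
    expect_equal(continuousJaccard(a, b), 0)
    expect_true(is.na(continuousJaccard(a * 0, b * 0)))
    ## bounded in [-1, 1] for random pairs
    for (i in 1:20) {
        x <- matrix(stats::rnorm(36), 9, 4); y <- matrix(stats::rnorm(36), 9, 4)
        j <- continuousJaccard(x, y)
        expect_gte(j, -1); expect_lte(j, 1)
    }
})

test_that("CWM reverse complement swaps complementary columns and reverses", {
    m <- matrix(seq_len(20), 5, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    rc <- cwmReverseComplement(m)
    expect_equal(unname(rc[1, "A"]), unname(m[5, "T"]))
    expect_equal(unname(rc[2, "C"]), unname(m[4, "G"]))
    expect_equal(cwmReverseComplement(rc), m)
})

test_that("scanning recovers a planted pattern at the right offset and strand", {
    lib <- defaultMotifLibrary()
    pwm <- lib$SOX$pwm
    cons <- pwmConsensus(pwm)
    pat <- pwm@matrix - 0.25
    pat <- pat / max(abs(pat))
    stats <- newSeqletStats("SOX", jaccard = c(0.2, 0.3, 0.4, 0.5),
                            l1 = c(5, 8, 12), ic = c(6, 7, 8))
    cwm <- newCWM("SOX", pat)
    mkTrack <- function(strand, offset, noise = 0.01, effect = 2,
                        seed = 88, width = 300) {
        set.seed(seed)
        s <- randomSequence(width, 0.45)
        planted <- if (strand == "-") rcSeq(cons) else cons
        substr(s, offset + 1, offset + nchar(cons)) <- planted
        bIdx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
        m <- matrix(0, width, 4)
        m[cbind(seq_len(width), bIdx)] <- stats::rnorm(width, 0, noise)
        p <- if (strand == "-") cwmReverseComplement(pat) else pat
        pos <- seq(offset + 1, offset + nchar(cons))
        m[cbind(pos, bIdx[pos])] <- effect * p[cbind(seq_along(pos), bIdx[pos])]
        newContributionTrack("t", m, s)
    }
    for (strand in c("+", "-")) {
        h <- cwmScan(mkTrack(strand, 100), cwm, stats, pwm)
        expect_equal(nrow(h), 1L)               # exactly one hit
        expect_equal(h$start, 100)              # at the planted offset
        expect_identical(h$strand, strand)      # on the planted strand
        expect_true(h$jaccard_pctl >= 0 && h$jaccard_pctl <= 100)
        expect_equal(h$ic_score, pwmIcScore(cons, pwm))  # consensus score
        expect_equal(h$ic_pctl, 100)
    }
    ## an all-zero track yields no hits
    zero <- newContributionTrack("z", matrix(0, 300, 4), randomSequence(300))
    expect_equal(nrow(cwmScan(zero, cwm, stats)), 0L)
    ## raising the Jaccard threshold never increases the hit count
    tr <- mkTrack("+", 100)
    nHits <- vapply(c(0, 0.5, 0.9), function(q) {
        stHigh <- newSeqletStats("SOX", stats@jaccard + q * (1 - stats@jaccard),
                                 stats@l1, stats@ic)
        nrow(cwmScan(tr, cwm, stHigh))
    }, numeric(1))
    expect_true(all(diff(nHits) <= 0))
    ## a CWM longer than the track is a domain error
    short <- newContributionTrack("s", diag(4)[, 1:4] * 0.5, "ACGT")
    expect_error(cwmScan(short, cwm, stats), "longer")
})

test_that("scanning a reverse-complemented track mirrors the hit set", {
    set.seed(13)
    cfg <- synthConfig(nRegions = 8, bystanderRate = 0, seed = 77)
    sim <- simulateRegions(cfg)
    sc <- syntheticContributions(sim)
    checked <- 0L
    for (id in names(sc$tracks)) {
        tr <- sc$tracks[[id]]
        W <- nrow(tr@matrix)
        rc <- newContributionTrack(id, cwmReverseComplement(tr@matrix),
                                   rcSeq(tr@sequence))
        for (nm in names(sc$stats)) {
            h <- cwmScan(tr, sc$cwms[[nm]], sc$stats[[nm]])
            hr <- cwmScan(rc, sc$cwms[[nm]], sc$stats[[nm]])
            expect_equal(nrow(h), nrow(hr))
            if (nrow(h)) {
                checked <- checked + nrow(h)
                expect_equal(sort(W - h$end), sort(hr$start))
                m <- merge(h, data.frame(start = W - hr$end,
                                         strandRc = hr$strand,
                                         jaccardRc = hr$jaccard))
                expect_true(all(m$strand != m$strandRc))
                expect_equal(m$jaccard, m$jaccardRc, tolerance = 1e-12)
            }
        }
    }
    expect_gt(checked, 5)  # the fixture actually exercised the property
})

test_that("overlap resolution drops redundant and palindromic duplicates", {
    hit <- function(region, start, end, strand, motif, jaccard, l1)
        data.frame(region = region, start = start, end = end,
                   strand = strand, motif = motif, jaccard = jaccard,
                   jaccard_pctl = 50, l1 = l1, ic_score = NA_real_,
                   ic_pctl = NA_real_)
    hits <- rbind(
        hit("r1", 100, 115, "+", "OCTSOX", 0.8, 5.0),  # composite, larger L1
        hit("r1", 104, 113, "-", "SOX", 0.9, 2.0),     # embedded submotif
        hit("r1", 300, 309, "+", "SOX", 0.7, 3.0),     # palindromic pair
        hit("r1", 300, 309, "-", "SOX", 0.7, 3.0),
        hit("r2", 50, 59, "+", "SOX", 0.6, 2.5))       # untouched
    res <- resolveOverlaps(hits, redundancyMap = list(c("OCTSOX", "SOX")))
    expect_equal(nrow(res), 3L)
    expect_true(any(res$motif == "OCTSOX"))
    expect_false(any(res$motif == "SOX" & res$region == "r1" & res$start == 104))
    pal <- res[res$start == 300, ]
    expect_equal(nrow(pal), 1L)
    expect_identical(pal$strand, "+")  # tie goes to the plus strand
    expect_true(any(res$region == "r2"))
    ## idempotence
    expect_identical(resolveOverlaps(res, list(c("OCTSOX", "SOX"))), res)
    ## non-overlapping hits pass through unchanged
    clean <- rbind(hit("r1", 10, 19, "+", "SOX", 0.9, 3),
                   hit("r1", 100, 109, "+", "SOX", 0.8, 3))
    expect_equal(nrow(resolveOverlaps(clean)), 2L)
    ## unknown motif in the redundancy map is a configuration error
    expect_error(resolveOverlaps(hits, list(c("SOX", "NOPE")),
                                 knownMotifs = c("SOX", "OCTSOX")),
                 "unknown motif")
})

test_that("information-content PWM scores have the stated limits and ordering", {
    unif <- newPWM("U", matrix(0.25, 6, 4))
    expect_equal(pwmIcScore("ACGTAC", unif), 0)
    ## deterministic PWM scores 2L on its consensus
    det <- matrix(1e-12, 5, 4); det[, 2] <- 1 - 3e-12
    det <- det / rowSums(det)
    pw <- newPWM("C5", det)
    expect_equal(pwmIcScore("CCCCC", pw), 10, tolerance = 1e-6)
    expect_error(pwmIcScore("CCC", pw), "length")
    ## graded mismatches score monotonically
    lib <- defaultMotifLibrary()
    pwm <- lib$SOX$pwm
    cons <- pwmConsensus(pwm)
    one <- cons; substr(one, 3, 3) <- "T"
    two <- one; substr(two, 7, 7) <- "A"
    s <- c(pwmIcScore(cons, pwm), pwmIcScore(one, pwm), pwmIcScore(two, pwm))
    expect_true(all(diff(s) < 0))
    ## the matched-base-only variant agrees on consensus ordering
    sm <- c(pwmIcScore(cons, pwm, method = "match"),
            pwmIcScore(two, pwm, method = "match"))
    expect_true(diff(sm) < 0)
    ## percentiles
    expect_equal(percentileOf(5, 1:10), 50)
    expect_equal(percentileOf(100, 1:10), 100)
})
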