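## Synthetic ground-truth generator: toy accessible regions with planted
## motifs of graded affinity, a sequence->log-counts predictor with
## tunable distance-dependent superadditivity, and emulated contribution
## tracks + seqlet statistics for scanner validation.

#' Default synthetic motif library
#'
#' Three pioneer motifs of graded length (a Sox2-like 9-mer, a composite
#' Oct4-Sox2-like 15-mer and a Klf4-like 10-mer) plus one non-pioneer
#' bystander motif. Each pioneer carries three affinity tiers realized as
#' controlled numbers of consensus mismatches (0/1/2) mapped to
#' counts-space effect-size ranges; bystanders plant with zero effect.
#'
#' @return named list; each element has `pwm` ([PWM-class]), `pioneer`
#'   flag and a `tiers` list of `list(mismatches, effect = c(lo, hi))`.
#' @export
defaultMotifLibrary <- function() {
    mk <- function(name, consensus, p = 0.85) {
        b <- match(strsplit(consensus, "")[[1]], .BASES)
        m <- matrix((1 - p) / 3, nrow = length(b), ncol = 4L)
        m[cbind(seq_along(b), b)] <- p
        newPWM(name, m)
    }
    tiers <- list(
        high = list(mismatches = 0L, effect = c(1.5, 2.5)),
        medium = list(mismatches = 1L, effect = c(0.7, 1.2)),
        low = list(mismatches = 2L, effect = c(0.25, 0.5))
    )
    list(
        SOX = list(pwm = mk("SOX", "GACAAAGGG"), pioneer = TRUE, tiers = tiers),
        OCTSOX = list(pwm = mk("OCTSOX", "ATTTGCATAACAATG"), pioneer = TRUE,
                      tiers = tiers),
        KLF = list(pwm = mk("KLF", "GGGGTGGGGC"), pioneer = TRUE, tiers = tiers),
        BYST = list(pwm = mk("BYST", "TAATGGGC"), pioneer = FALSE,
                    tiers = list(high = list(mismatches = 0L,
                                             effect = c(0, 0))))
    )
}

#' Configuration of the synthetic-data generator
#'
#' @param nRegions number of regions.
#' @param regionLength region width in bp (default 1000, the accessible-
#'   region scale the generator emulates).
#' @param gc background GC target.
#' @param motifLibrary library from [defaultMotifLibrary()].
#' @param arrangement `"grouped"` (pioneer anchor plus a partner at a
#'   sampled pair distance) or `"single"` (one pioneer per region).
#' @param pairDistance `c(lo, hi)` center-to-center distance range (bp)
#'   for grouped arrangements.
#' @param anchorTier tier of the anchor motif in grouped arrangements.
#' @param kappa0,tau,cutoff interaction kernel: pairs at center distance
#'   `d < cutoff` interact with strength `kappa0 * exp(-d / tau)`, zero
#'   beyond; the 200 bp default cutoff mirrors the intra-nucleosomal
#'   range of pioneering cooperativity.
#' @param baseCounts baseline predicted counts of a motif-free region.
#' @param matchThreshold identity below which a planted motif is
#'   considered fully ablated by the predictor (degradation tolerance).
#' @param countsNoise log-normal noise scale on predicted counts
#'   (0 = deterministic; nonzero noise is hashed from the sequence so
#'   the predictor contract stays deterministic).
#' @param contribNoise Gaussian noise scale on contribution tracks.
#' @param seqletNoise additive noise scale used when fabricating seqlets.
#' @param bystanderRate probability of planting a zero-effect bystander
#'   motif per region.
#' @param seed integer seed.
#' @return list of class `SynthConfig`.
#' @export
synthConfig <- function(nRegions = 100L, regionLength = 1000L, gc = 0.42,
                        motifLibrary = defaultMotifLibrary(),
                        arrangement = c("grouped", "single"),
                        pairDistance = c(20, 180), anchorTier = "high",
                        kappa0 = 1, tau = 200, cutoff = 200,
                        baseCounts = 100, matchThreshold = 0.5,
                        countsNoise = 0, contribNoise = 0.05,
                        seqletNoise = 0.5, bystanderRate = 0.5,
                        seed = 1L) {
    arrangement <- match.arg(arrangement)
    stopifnot(nRegions >= 1, regionLength >= 50, gc > 0, gc < 1,
              kappa0 >= 0, tau > 0, cutoff <= regionLength,
              pairDistance[1] <= pairDistance[2], baseCounts > 0,
              matchThreshold >= 0, matchThreshold < 1)
    maxL <- max(vapply(motifLibrary, function(m) nrow(m$pwm@matrix),
                       integer(1)))
    if (maxL > regionLength) stop("motif longer than the region")
    cfg <- list(nRegions = as.integer(nRegions),
                regionLength = as.integer(regionLength), gc = gc,
                motifLibrary = motifLibrary, arrangement = arrangement,
                pairDistance = pairDistance, anchorTier = anchorTier,
                kappa0 = kappa0, tau = tau, cutoff = cutoff,
                baseCounts = baseCounts, matchThreshold = matchThreshold,
                countsNoise = countsNoise, contribNoise = contribNoise,
                seqletNoise = seqletNoise, bystanderRate = bystanderRate,
                seed = as.integer(seed))
    class(cfg) <- "SynthConfig"
    cfg
}

## Plant `mismatches` random substitutions into a consensus string.
.degradeConsensus <- function(consensus, mismatches) {
    b <- strsplit(consensus, "")[[1]]
    if (mismatches > 0L) {
        pos <- sample.int(length(b), mismatches)
        for (p in pos) b[p] <- sample(setdiff(.BASES, b[p]), 1L)
    }
    paste(b, collapse = "")
}

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate regions with planted motifs and known ground truth
#'
#' Backgrounds are drawn at the target GC; pioneer motif instances are
#' planted with tier-controlled consensus mismatches, random strand and
#' tier-dependent effect sizes; grouped arrangements place a partner
#' motif at a sampled center-to-center distance from the anchor, giving
#' the pair an interaction `kappa(d)` from the configured kernel.
#' Bystander motifs plant with zero effect. Fully reproducible by seed.
#'
#' @param config a `SynthConfig` from [synthConfig()].
#' @param seed integer; defaults to the config seed.
#' @return list of class `SyntheticRegions`: `sequences` (named character
#'   vector), `truth` (list with `motifs` and `pairs` data.frames) and
#'   `config`.
#' @export
simulateRegions <- function(config, seed = config$seed) {
    stopifnot(inherits(config, "SynthConfig"))
    lib <- config$motifLibrary
    pioneers <- names(Filter(function(m) m$pioneer, lib))
    bystanders <- names(Filter(function(m) !m$pioneer, lib))
    W <- config$regionLength

    .withSeed(seed, {
        seqs <- character(config$nRegions)
        motifRows <- list()
        pairRows <- list()
        for (r in seq_len(config$nRegions)) {
            id <- sprintf("region_%04d", r)
            s <- randomSequence(W, config$gc)
            spans <- matrix(numeric(0), ncol = 2)

            plant <- function(motifName, tier, center) {
                entry <- lib[[motifName]]
                tierSpec <- entry$tiers[[tier]]
                L <- nrow(entry$pwm@matrix)
                start <- round(center - L / 2)            # 0-based
                planted <- .degradeConsensus(pwmConsensus(entry$pwm),
                                             tierSpec$mismatches)
                strand <- sample(c("+", "-"), 1L)
                inRegion <- if (strand == "-") .revcomp(planted) else planted
                effect <- stats::runif(1, tierSpec$effect[1],
                                       tierSpec$effect[2])
                list(region = id, start = start, end = start + L,
                     strand = strand, motif = motifName, tier = tier,
                     effect = effect, plantedSeq = inRegion)
            }
            fits <- function(m) {
                m$start >= 0 && m$end <= W &&
                    !any(spans[, 1] < m$end & m$start < spans[, 2])
            }
            addMotif <- function(m) {
                spans <<- rbind(spans, c(m$start, m$end))
                substr(s, m$start + 1L, m$end) <<- m$plantedSeq
                motifRows[[length(motifRows) + 1L]] <<- as.data.frame(
                    m, stringsAsFactors = FALSE)
                length(motifRows)
            }

            anchorMotif <- sample(pioneers, 1L)
            tierNames <- names(lib[[anchorMotif]]$tiers)
            if (config$arrangement == "grouped") {
                anchorCenter <- stats::runif(1, 150, min(450, W - 150))
                a <- plant(anchorMotif, config$anchorTier, anchorCenter)
                ia <- addMotif(a)
                partnerMotif <- sample(pioneers, 1L)
                d <- stats::runif(1, config$pairDistance[1],
                                  config$pairDistance[2])
                pm <- plant(partnerMotif, sample(tierNames, 1L),
                            anchorCenter + d)
                if (!fits(pm))
                    pm <- plant(partnerMotif, sample(tierNames, 1L),
                                anchorCenter - d)
                if (fits(pm)) {
                    ib <- addMotif(pm)
                    kap <- if (d < config$cutoff)
                        config$kappa0 * exp(-d / config$tau) else 0
                    pairRows[[length(pairRows) + 1L]] <- data.frame(
                        region = id, idxA = ia, idxB = ib,
                        distance = d, kappa = kap)
                }
            } else {
                a <- plant(anchorMotif, sample(tierNames, 1L),
                           stats::runif(1, 100, W - 100))
                addMotif(a)
            }
            if (length(bystanders) && stats::runif(1) < config$bystanderRate) {
                for (try in 1:10) {
                    bm <- plant(sample(bystanders, 1L), "high",
                                stats::runif(1, 50, W - 50))
                    if (fits(bm)) { addMotif(bm); break }
                }
            }
            seqs[r] <- s
            names(seqs)[r] <- id
        }
        truth <- list(
            motifs = do.call(rbind, motifRows),
            pairs = if (length(pairRows)) do.call(rbind, pairRows)
                    else data.frame(region = character(), idxA = integer(),
                                    idxB = integer(), distance = numeric(),
                                    kappa = numeric())
        )
        structure(list(sequences = seqs, truth = truth, config = config),
                  class = "SyntheticRegions")
    })
}

## Identity-based, degradation-tolerant match of a planted span in the
## queried sequence: 1 for the intact planted bases, ramping to 0 below
## the identity threshold (so random replacement ablates the term).
.spanMatch <- function(sequence, start, end, plantedSeq, thr) {
    cur <- substr(sequence, start + 1L, end)
    if (nchar(cur) != nchar(plantedSeq)) return(0)
    id <- mean(utf8ToInt(cur) == utf8ToInt(plantedSeq))
    max(0, min(1, (id - thr) / (1 - thr)))
}

#' Synthetic predictor over simulated regions
#'
#' Builds a [Predictor-class] implementing, for a query on a known
#' region, `counts = base * prod_m (1 + e_m * match_m) * prod_pairs
#' (1 + kappa(d) * match_A * match_B)` (returned as natural-log counts),
#' where `match_m` is a degradation-tolerant identity match of the
#' planted span against the queried sequence -- so in situ mutations
#' ablate the corresponding terms. `mode = "additive"` replaces the
#' products with `counts = base * (1 + sum_m e_m * match_m)`, a strictly
#' additive-in-counts null with zero cooperativity by construction.
#' Querying an unknown region is an error.
#'
#' @param sim a `SyntheticRegions` object from [simulateRegions()].
#' @param mode `"multiplicative"` (default) or `"additive"`.
#' @return a [Predictor-class].
#' @export
syntheticPredictor <- function(sim, mode = c("multiplicative", "additive")) {
    mode <- match.arg(mode)
    stopifnot(inherits(sim, "SyntheticRegions"))
    cfg <- sim$config
    motifs <- sim$truth$motifs
    pairs <- sim$truth$pairs
    byRegion <- split(seq_len(nrow(motifs)), motifs$region)
    pairsByRegion <- if (nrow(pairs)) split(seq_len(nrow(pairs)),
                                            pairs$region) else list()
    thr <- cfg$matchThreshold

    fun <- function(sequence, region = NULL) {
        if (is.null(region) || !region %in% names(byRegion))
            stop("lookup error: unknown region '",
                 if (is.null(region)) "<NULL>" else region, "'")
        idx <- byRegion[[region]]
        match <- vapply(idx, function(i) {
            .spanMatch(sequence, motifs$start[i], motifs$end[i],
                       motifs$plantedSeq[i], thr)
        }, numeric(1))
        eff <- motifs$effect[idx]
        counts <- if (mode == "multiplicative") {
            base <- cfg$baseCounts * prod(1 + eff * match)
            if (!is.null(pairsByRegion[[region]])) {
                for (j in pairsByRegion[[region]]) {
                    mA <- match[idx == pairs$idxA[j]]
                    mB <- match[idx == pairs$idxB[j]]
                    base <- base * (1 + pairs$kappa[j] * mA * mB)
                }
            }
            base
        } else {
            cfg$baseCounts * (1 + sum(eff * match))
        }
        if (cfg$countsNoise > 0) {
            ## deterministic per-sequence noise: hash the sequence
            h <- sum(utf8ToInt(sequence) * seq_len(nchar(sequence))) %%
                .Machine$integer.max
            z <- .withSeed(as.integer((h + cfg$seed) %% .Machine$integer.max),
                           stats::rnorm(1))
            counts <- counts * exp(cfg$countsNoise * z)
        }
        log(counts)
    }
    newPredictor(fun, inputWidth = cfg$regionLength,
                 outputWidth = cfg$regionLength)
}

#' Substring-detection predictor for injection experiments
#'
#' A [Predictor-class] that multiplies the baseline counts by
#' `(1 + effect)` for every listed motif sequence found verbatim anywhere
#' in the query -- the injection-aware counterpart of
#' [syntheticPredictor()], usable on arbitrary backgrounds.
#'
#' @param motifTable data.frame with columns `seq` and `effect`.
#' @param baseCounts baseline counts.
#' @param width predictor input/output width.
#' @return a [Predictor-class].
#' @export
motifInjectionPredictor <- function(motifTable, baseCounts = 100,
                                    width = 1000L) {
    stopifnot(all(c("seq", "effect") %in% names(motifTable)))
    fun <- function(sequence, region = NULL) {
        present <- vapply(motifTable$seq, grepl, logical(1), x = sequence,
                          fixed = TRUE, USE.NAMES = FALSE)
        log(baseCounts * prod(1 + motifTable$effect[present]))
    }
    newPredictor(fun, inputWidth = width, outputWidth = width)
}

## CWM pattern of a motif: mean-centered PWM scaled to max |weight| 1.
.cwmPattern <- function(pwm) {
    w <- pwm@matrix - 0.25
    w / max(abs(w))
}

#' Synthetic contribution tracks and seqlet statistics
#'
#' Emulates the model-interpretation outputs that CWM scanning consumes:
#' each region's track carries the effect-scaled CWM pattern at the
#' observed bases of planted pioneer spans (reverse-complemented on the
#' minus strand) on top of Gaussian noise of scale `contribNoise` over
#' all observed bases; bystander spans receive no signal beyond noise. Seqlet statistics per motif are
#' fabricated by re-sampling the planted instances with magnitude jitter
#' and additive noise, then scoring them exactly as the scanner would
#' (orientation-maximal Jaccard, L1 magnitude, information content).
#'
#' @param sim a `SyntheticRegions` object.
#' @param seed integer; defaults to the config seed plus one.
#' @return list: `tracks` (list of [ContributionTrack-class]), `stats`
#'   (named list of [SeqletStats-class]), `cwms` (named list of
#'   [CWM-class]) and `pwms`.
#' @export
syntheticContributions <- function(sim, seed = sim$config$seed + 1L) {
    stopifnot(inherits(sim, "SyntheticRegions"))
    cfg <- sim$config
    lib <- cfg$motifLibrary
    motifs <- sim$truth$motifs
    patterns <- lapply(lib, function(m) .cwmPattern(m$pwm))

    .withSeed(seed, {
        tracks <- lapply(names(sim$sequences), function(id) {
            s <- sim$sequences[[id]]
            W <- nchar(s)
            bIdx <- match(strsplit(s, "")[[1]], .BASES)
            m <- matrix(0, W, 4L, dimnames = list(NULL, .BASES))
            if (cfg$contribNoise > 0)
                m[cbind(seq_len(W), bIdx)] <- stats::rnorm(W, 0, cfg$contribNoise)
            rows <- which(motifs$region == id & motifs$effect > 0)
            for (i in rows) {
                pat <- patterns[[motifs$motif[i]]]
                if (motifs$strand[i] == "-") pat <- cwmReverseComplement(pat)
                pos <- seq(motifs$start[i] + 1L, motifs$end[i])
                m[cbind(pos, bIdx[pos])] <- m[cbind(pos, bIdx[pos])] +
                    motifs$effect[i] * pat[cbind(seq_along(pos), bIdx[pos])]
            }
            newContributionTrack(id, m, s)
        })
        names(tracks) <- names(sim$sequences)

        cwms <- lapply(names(lib), function(nm)
            newCWM(nm, patterns[[nm]],
                   nSeqlets = sum(motifs$motif == nm & motifs$effect > 0)))
        names(cwms) <- names(lib)
        pwms <- lapply(lib, function(m) m$pwm)

        stats <- lapply(names(lib), function(nm) {
            rows <- which(motifs$motif == nm & motifs$effect > 0)
            if (!length(rows)) return(NULL)
            fwd <- patterns[[nm]]
            L <- nrow(fwd)
            sc <- lapply(rows, function(i) {
                pat <- if (motifs$strand[i] == "-")
                    cwmReverseComplement(fwd) else fwd
                bIdx <- match(strsplit(motifs$plantedSeq[i], "")[[1]], .BASES)
                win <- matrix(0, L, 4L)
                jitter <- stats::runif(1, 0.4, 1)
                scale <- jitter * motifs$effect[i]
                ## shape noise proportional to the seqlet's own signal, so
                ## seqlet Jaccards sit below clean-track values while seqlet
                ## L1 magnitudes stay below the weakest planted instances
                win[cbind(seq_len(L), bIdx)] <-
                    scale * (pat[cbind(seq_len(L), bIdx)] +
                             stats::rnorm(L, 0, cfg$seqletNoise))
                nwin <- win / max(sum(abs(win)), .Machine$double.eps)
                ncwm <- fwd / sum(abs(fwd))
                j <- max(continuousJaccard(ncwm, nwin),
                         continuousJaccard(cwmReverseComplement(ncwm), nwin))
                motifSeq <- if (motifs$strand[i] == "-")
                    .revcomp(motifs$plantedSeq[i]) else motifs$plantedSeq[i]
                c(jaccard = j, l1 = sum(abs(win)),
                  ic = pwmIcScore(motifSeq, lib[[nm]]$pwm))
            })
            sc <- do.call(rbind, sc)
            newSeqletStats(nm, sc[, "jaccard"], sc[, "l1"], sc[, "ic"])
        })
        names(stats) <- names(lib)
        stats <- Filter(Negate(is.null), stats)

        list(tracks = tracks, stats = stats, cwms = cwms, pwms = pwms)
    })
}

#' Simulate a cooperativity benchmark of motif pairs
#'
#' Generates `nPairs` regions, each holding one anchor/partner pioneer
#' pair at a center-to-center distance drawn uniformly from
#' `distanceRange` (spanning well beyond the interaction cutoff so the
#' far reference group is populated), scores every pair with
#' [pairwiseCooperativity()] against the multiplicative synthetic
#' predictor, and returns the records joined with the true interaction
#' strengths.
#'
#' @param nPairs number of motif pairs (one per region).
#' @param nTrials ablation trials per mutated scenario.
#' @param distanceRange `c(lo, hi)` pair-distance range in bp.
#' @param seed integer seed.
#' @param ... overrides forwarded to [synthConfig()].
#' @return data.frame of cooperativity records with columns from
#'   [pairwiseCooperativity()] plus `kappa` (true interaction).
#' @export
simulateCoopBenchmark <- function(nPairs = 5000L, nTrials = 16L,
                                  distanceRange = c(10, 500), seed = 1L,
                                  ...) {
    cfg <- synthConfig(nRegions = nPairs, arrangement = "grouped",
                       pairDistance = distanceRange, bystanderRate = 0,
                       seed = seed, ...)
    sim <- simulateRegions(cfg)
    pred <- syntheticPredictor(sim)
    motifs <- sim$truth$motifs
    pairs <- sim$truth$pairs
    .withSeed(seed + 1L, {
        recs <- lapply(seq_len(nrow(pairs)), function(j) {
            iA <- pairs$idxA[j]; iB <- pairs$idxB[j]
            rec <- pairwiseCooperativity(
                pred, sim$sequences[[pairs$region[j]]],
                spanA = c(motifs$start[iA], motifs$end[iA]),
                spanB = c(motifs$start[iB], motifs$end[iB]),
                nTrials = nTrials, region = pairs$region[j])
            rec$kappa <- pairs$kappa[j]
            rec
        })
        do.call(rbind, recs)
    })
}
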