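#' @import methods
NULL

## ---------------------------------------------------------------------------
## Kinetic model containers
## ---------------------------------------------------------------------------

#' Kinetic parameters for one TF at one locus
#'
#' Holds every rate constant and modulation factor of the TF-nucleosome
#' kinetic model for a single TF. Concentration is absorbed into the
#' association rate, so changing TF concentration is simulated by changing
#' `kOn`.
#'
#' @slot kOn association rate (s^-1), concentration-absorbed; `kOn = 0`
#'   encodes the TF-absent limit.
#' @slot kOff non-specific unbinding rate from the open conformation without
#'   a motif (s^-1).
#' @slot g unitless affinity factor in (0, 1]; the motif reduces the
#'   open-state off rate to `g * kOff`, so 1/g is the motif affinity.
#' @slot betaN unitless factor >= 1 by which the nucleosome destabilizes
#'   non-specific binding (closed, no motif).
#' @slot betaM unitless factor >= 1 applied to the closed-state off rate when
#'   a motif is present (see [buildRateMatrix()] for the two conventions).
#' @slot kOpen basal chromatin opening rate (s^-1).
#' @slot d unitless nucleosome dissociation constant in (0, 1);
#'   `kClose = kOpen / d`, and baseline accessibility without TF is
#'   `d / (1 + d)`.
#' @slot o unitless factor >= 1 by which a bound TF increases the opening
#'   rate (nucleosome removal).
#' @slot c unitless factor >= 1 by which a bound TF attenuates the closing
#'   rate (nucleosome reformation); the effective closing rate is divided
#'   by `c`.
#' @slot motifPresent logical; whether the TF's motif is present at the
#'   locus.
#' @seealso [kineticParams()], [buildRateMatrix()], [steadyState()]
#' @export
setClass("KineticParams",
    representation(
        kOn = "numeric", kOff = "numeric", g = "numeric",
        betaN = "numeric", betaM = "numeric",
        kOpen = "numeric", d = "numeric",
        o = "numeric", c = "numeric",
        motifPresent = "logical"
    )
)

setValidity("KineticParams", function(object) {
    msg <- character()
    num1 <- function(x) length(x) == 1L && is.finite(x)
    for (s in c("kOn", "kOff", "g", "betaN", "betaM", "kOpen", "d", "o", "c")) {
        if (!num1(slot(object, s))) msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    }
    if (length(msg)) return(msg)
    if (object@kOn < 0) msg <- c(msg, "kOn must be >= 0")
    if (object@kOff <= 0) msg <- c(msg, "kOff must be > 0")
    if (object@kOpen <= 0) msg <- c(msg, "kOpen must be > 0")
    if (object@g <= 0 || object@g > 1) msg <- c(msg, "g must be in (0, 1]")
    if (object@betaN < 1) msg <- c(msg, "betaN must be >= 1")
    if (object@betaM < 1) msg <- c(msg, "betaM must be >= 1")
    if (object@o < 1) msg <- c(msg, "o must be >= 1")
    if (object@c < 1) msg <- c(msg, "c must be >= 1")
    if (object@d <= 0 || object@d >= 1) msg <- c(msg, "d must be in (0, 1)")
    if (length(object@motifPresent) != 1L || is.na(object@motifPresent))
        msg <- c(msg, "motifPresent must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' Construct a KineticParams object
#'
#' Defaults are the fixed values used throughout the simulations
#' (`kOn = 0.1`, `kOff = 1`, `kOpen = 0.05`, `betaN = 5` in s^-1 /
#' unitless as appropriate); the remaining factors default to mid-range
#' values and are normally drawn with [sampleParameterSets()].
#'
#' @param kOn,kOff,g,betaN,betaM,kOpen,d,o,c,motifPresent see
#'   [KineticParams-class].
#' @return A [KineticParams-class] object.
#' @examples
#' kineticParams(g = 0.01, o = 20, c = 2, d = 0.01)
#' @export
kineticParams <- function(kOn = 0.1, kOff = 1, g = 0.03, betaN = 5,
                          betaM = 5, kOpen = 0.05, d = 0.01,
                          o = 10, c = 2, motifPresent = TRUE) {
    new("KineticParams",
        kOn = as.numeric(kOn), kOff = as.numeric(kOff), g = as.numeric(g),
        betaN = as.numeric(betaN), betaM = as.numeric(betaM),
        kOpen = as.numeric(kOpen), d = as.numeric(d),
        o = as.numeric(o), c = as.numeric(c),
        motifPresent = as.logical(motifPresent))
}

setMethod("show", "KineticParams", function(object) {
    cat("KineticParams (", if (object@motifPresent) "motif present" else "no motif",
        ")\n", sep = "")
    cat(sprintf("  kOn=%.4g kOff=%.4g g=%.4g betaN=%.4g betaM=%.4g\n",
                object@kOn, object@kOff, object@g, object@betaN, object@betaM))
    cat(sprintf("  kOpen=%.4g d=%.4g (kClose=%.4g) o=%.4g c=%.4g\n",
                object@kOpen, object@d, object@kOpen / object@d,
                object@o, object@c))
})

#' Labeled transition-rate matrix of the TF-nucleosome chain
#'
#' Column-Laplacian convention: entry (i, j) holds the transition rate from
#' state j to state i for i != j, and each diagonal entry is the negative
#' column sum, so every column sums to zero. States are (conformation x
#' per-TF occupancy) tuples.
#'
#' @slot matrix square numeric matrix, dimnames = state labels.
#' @slot states data.frame with one row per state: `label`, `conformation`
#'   ("closed"/"open") and one logical `bound.<k>` column per TF.
#' @slot nTfs integer, 1 or 2.
#' @export
setClass("RateMatrix",
    representation(matrix = "matrix", states = "data.frame", nTfs = "integer")
)

setValidity("RateMatrix", function(object) {
    m <- object@matrix
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    if (nrow(m) != nrow(object@states)) msg <- c(msg, "states/matrix size mismatch")
    off <- m; diag(off) <- 0
    if (any(off < 0)) msg <- c(msg, "off-diagonal rates must be >= 0")
    if (max(abs(colSums(m))) > 1e-12 * max(1, max(abs(m))))
        msg <- c(msg, "columns must sum to 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "RateMatrix", function(object) {
    cat(sprintf("RateMatrix: %d states, %d TF(s)\n",
                nrow(object@matrix), object@nTfs))
    print(signif(object@matrix, 4))
})

#' @describeIn RateMatrix-class the underlying numeric matrix.
#' @param rm a `RateMatrix`.
#' @export
rateMatrix <- function(rm) rm@matrix

#' @describeIn RateMatrix-class the state table.
#' @export
stateSpace <- function(rm) rm@states

## ---------------------------------------------------------------------------
## Predictor contract
## ---------------------------------------------------------------------------

#' Sequence-to-log-counts predictor contract
#'
#' A `Predictor` wraps any deterministic function mapping a fixed-width
#' A/C/G/T sequence to the predicted log total counts over its output
#' window (the role played by a trained accessibility model). All scoring
#' functions ([isolationScore()], [contextScore()],
#' [pairwiseCooperativity()]) operate against this contract.
#'
#' @slot fun `function(sequence, region = NULL)` returning a single real
#'   log-counts value; `region` carries a region identifier for predictors
#'   that are keyed to known regions (e.g. [syntheticPredictor()]).
#' @slot inputWidth,outputWidth widths in bp (default 1000).
#' @export
setClass("Predictor",
    representation(fun = "function", inputWidth = "integer",
                   outputWidth = "integer")
)

#' Construct a Predictor
#'
#' @param fun function of `(sequence, region)` returning predicted log
#'   total counts (natural log scale).
#' @param inputWidth,outputWidth widths in bp.
#' @return A [Predictor-class].
#' @examples
#' p <- newPredictor(function(sequence, region = NULL) log(100))
#' predictLogCounts(p, "ACGT")
#' @export
newPredictor <- function(fun, inputWidth = 1000L, outputWidth = 1000L) {
    new("Predictor", fun = fun, inputWidth = as.integer(inputWidth),
        outputWidth = as.integer(outputWidth))
}

#' Predict log total counts for a sequence
#'
#' @param predictor a [Predictor-class].
#' @param sequence A/C/G/T string.
#' @param region optional region identifier passed through to the
#'   predictor.
#' @return numeric scalar, log total counts.
#' @export
predictLogCounts <- function(predictor, sequence, region = NULL) {
    stopifnot(is(predictor, "Predictor"))
    predictor@fun(sequence, region)
}

setMethod("show", "Predictor", function(object) {
    cat(sprintf("Predictor: input %d bp -> log counts over %d bp window\n",
                object@inputWidth, object@outputWidth))
})

## ---------------------------------------------------------------------------
## Backgrounds
## ---------------------------------------------------------------------------

#' A set of matched, dinucleotide-shuffled background sequences
#'
#' @slot sequences character vector of shuffled background sequences.
#' @slot gcTarget,cpgTarget targets used for pool matching.
#' @slot seed integer seed used for sampling and shuffling.
#' @seealso [generateBackgrounds()]
#' @export
setClass("BackgroundSet",
    representation(sequences = "character", gcTarget = "numeric",
                   cpgTarget = "numeric", seed = "integer")
)

setMethod("show", "BackgroundSet", function(object) {
    cat(sprintf("BackgroundSet: %d sequences of %d bp (GC target %.3f)\n",
                length(object@sequences),
                if (length(object@sequences)) nchar(object@sequences[1]) else 0L,
                object@gcTarget))
})

#' @describeIn BackgroundSet-class number of background sequences.
#' @param x a `BackgroundSet`.
#' @export
setMethod("length", "BackgroundSet", function(x) length(x@sequences))

#' @describeIn BackgroundSet-class the background sequences.
#' @param object a `BackgroundSet`.
#' @export
backgroundSequences <- function(object) object@sequences

## ---------------------------------------------------------------------------
## Motif-mapping containers
## ---------------------------------------------------------------------------

.BASES <- c("A", "C", "G", "T")

#' Contribution weight matrix (CWM)
#'
#' Signed per-base contribution weights averaged over supporting seqlets;
#' the motif representation used for scanning contribution tracks.
#'
#' @slot name motif name.
#' @slot matrix L x 4 numeric matrix, columns A, C, G, T.
#' @slot nSeqlets number of supporting seqlets (metadata).
#' @export
setClass("CWM",
    representation(name = "character", matrix = "matrix", nSeqlets = "integer")
)

setValidity("CWM", function(object) {
    m <- object@matrix
    if (ncol(m) != 4L) return("matrix must have 4 columns (A,C,G,T)")
    if (nrow(m) < 4L) return("motif length must be >= 4")
    if (all(m == 0)) return("at least one entry must be nonzero")
    TRUE
})

#' Construct a CWM
#' @param name motif name.
#' @param matrix L x 4 numeric matrix (columns A,C,G,T).
#' @param nSeqlets supporting seqlet count.
#' @export
newCWM <- function(name, matrix, nSeqlets = NA_integer_) {
    colnames(matrix) <- .BASES
    new("CWM", name = name, matrix = matrix, nSeqlets = as.integer(nSeqlets))
}

setMethod("show", "CWM", function(object) {
    cat(sprintf("CWM '%s': %d bp, %s seqlets\n", object@name,
                nrow(object@matrix),
                ifelse(is.na(object@nSeqlets), "?", object@nSeqlets)))
})

#' Position weight matrix (PWM)
#'
#' Per-position nucleotide probabilities. Throughout the package "PWM
#' score" means the information-content match score, not log-odds.
#'
#' @slot name motif name.
#' @slot matrix L x 4 probability matrix, rows summing to 1.
#' @export
setClass("PWM", representation(name = "character", matrix = "matrix"))

setValidity("PWM", function(object) {
    m <- object@matrix
    if (ncol(m) != 4L) return("matrix must have 4 columns (A,C,G,T)")
    if (any(m < 0) || any(m > 1)) return("entries must be probabilities")
    if (max(abs(rowSums(m) - 1)) > 1e-9) return("rows must sum to 1")
    TRUE
})

#' Construct a PWM
#' @param name motif name.
#' @param matrix L x 4 probability matrix.
#' @export
newPWM <- function(name, matrix) {
    colnames(matrix) <- .BASES
    new("PWM", name = name, matrix = matrix)
}

setMethod("show", "PWM", function(object) {
    cat(sprintf("PWM '%s': %d bp, consensus %s\n", object@name,
                nrow(object@matrix), pwmConsensus(object)))
})

#' Consensus sequence of a PWM
#' @param pwm a [PWM-class].
#' @return character consensus string.
#' @export
pwmConsensus <- function(pwm) {
    paste(.BASES[apply(pwm@matrix, 1L, which.max)], collapse = "")
}

#' Seqlet score distributions for one motif
#'
#' Distributions of continuous-Jaccard similarity, L1 contribution
#' magnitude and PWM information-content score over the seqlets that
#' support a motif. They define the scanning acceptance thresholds: a hit
#' requires Jaccard above the 20th seqlet percentile and L1 above the
#' minimum seqlet contribution.
#'
#' @slot motif motif name.
#' @slot jaccard,l1,ic numeric vectors (one value per seqlet).
#' @export
setClass("SeqletStats",
    representation(motif = "character", jaccard = "numeric",
                   l1 = "numeric", ic = "numeric")
)

setValidity("SeqletStats", function(object) {
    if (!length(object@jaccard) || !length(object@l1))
        return("seqlet distributions must be non-empty")
    TRUE
})

#' Construct SeqletStats
#' @param motif motif name.
#' @param jaccard,l1,ic per-seqlet score vectors.
#' @export
newSeqletStats <- function(motif, jaccard, l1, ic = numeric()) {
    new("SeqletStats", motif = motif, jaccard = as.numeric(jaccard),
        l1 = as.numeric(l1), ic = as.numeric(ic))
}

#' @describeIn SeqletStats-class the Jaccard acceptance threshold
#'   (20th percentile of the seqlet Jaccard distribution by default).
#' @param stats a `SeqletStats`.
#' @param prob percentile as a probability.
#' @export
jaccardThreshold <- function(stats, prob = 0.2) {
    unname(stats::quantile(stats@jaccard, prob))
}

#' @describeIn SeqletStats-class the L1 acceptance threshold (minimum
#'   seqlet contribution magnitude).
#' @export
l1Threshold <- function(stats) min(stats@l1)

setMethod("show", "SeqletStats", function(object) {
    cat(sprintf(
        "SeqletStats '%s': %d seqlets; jaccard 20th pctl %.3f, L1 min %.3g\n",
        object@motif, length(object@jaccard),
        jaccardThreshold(object), l1Threshold(object)))
})

#' Per-base contribution track for one region
#'
#' An L x 4 matrix of actual contribution values: only the column of the
#' observed base may be nonzero at each position, mirroring counts
#' contribution scores over a region.
#'
#' @slot regionId region identifier.
#' @slot matrix L x 4 numeric matrix (columns A,C,G,T).
#' @slot sequence the underlying A/C/G/T sequence.
#' @export
setClass("ContributionTrack",
    representation(regionId = "character", matrix = "matrix",
                   sequence = "character")
)

setValidity("ContributionTrack", function(object) {
    m <- object@matrix
    if (ncol(m) != 4L) return("matrix must have 4 columns (A,C,G,T)")
    if (nrow(m) != nchar(object@sequence))
        return("matrix rows must match sequence length")
    idx <- match(strsplit(object@sequence, "")[[1]], .BASES)
    if (anyNA(idx)) return("sequence must be over A/C/G/T")
    off <- m
    off[cbind(seq_len(nrow(m)), idx)] <- 0
    if (any(off != 0))
        return("only the observed base may carry contribution at each position")
    TRUE
})

#' Construct a ContributionTrack
#' @param regionId region identifier.
#' @param matrix L x 4 numeric matrix, nonzero only at observed bases.
#' @param sequence underlying sequence.
#' @export
newContributionTrack <- function(regionId, matrix, sequence) {
    colnames(matrix) <- .BASES
    new("ContributionTrack", regionId = regionId, matrix = matrix,
        sequence = sequence)
}

setMethod("show", "ContributionTrack", function(object) {
    cat(sprintf("ContributionTrack '%s': %d bp, total |contribution| %.3g\n",
                object@regionId, nrow(object@matrix),
                sum(abs(object@matrix))))
})
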