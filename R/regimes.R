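## Parameter regimes: biologically plausible sampling ranges for the
## kinetic model, reproducible Monte-Carlo draws, JSON round trip.

#' Default sampling regime for kinetic parameters
#'
#' Fixed values and sampling ranges over plausible biological variation:
#' `kOn = 0.1` s^-1, `kOff = 1` s^-1, `kOpen = 0.05` s^-1 and `betaN = 5`
#' are fixed; `g` is log-uniform in \[0.001, 0.09\] (motif affinities from
#' very weak to cooperativity-boosted), `betaM` uniform in \[2, 10\], `d`
#' log-uniform in \[0.001, 0.05) (predominantly closed chromatin without
#' TF), and the TF remodeling factors default to `o` log-uniform in
#' \[1, 100\] and `c` log-uniform in \[1, 10\].
#'
#' @param ... named overrides: a scalar fixes a parameter, a length-2
#'   vector `c(low, high)` sets its range.
#' @param seed integer seed stored with the regime.
#' @return list of class `ParameterRegime` with elements `fixed`,
#'   `ranges`, `scale` (sampling scale per ranged parameter) and `seed`.
#' @examples
#' defaultRegime(o = c(2, 50), betaM = 5)
#' @export
defaultRegime <- function(..., seed = 1L) {
    regime <- list(
        fixed = list(kOn = 0.1, kOff = 1, kOpen = 0.05, betaN = 5),
        ranges = list(g = c(0.001, 0.09), betaM = c(2, 10),
                      d = c(0.001, 0.05), o = c(1, 100), c = c(1, 10)),
        scale = c(g = "log", betaM = "linear", d = "log",
                  o = "log", c = "log"),
        seed = as.integer(seed)
    )
    dots <- list(...)
    for (nm in names(dots)) {
        if (!nm %in% c(names(regime$fixed), names(regime$ranges)))
            stop("unknown kinetic parameter: ", nm)
        v <- dots[[nm]]
        regime$fixed[[nm]] <- NULL
        regime$ranges[[nm]] <- NULL
        if (length(v) == 1L) regime$fixed[[nm]] <- v
        else if (length(v) == 2L) regime$ranges[[nm]] <- as.numeric(v)
        else stop("override for '", nm, "' must have length 1 or 2")
    }
    class(regime) <- "ParameterRegime"
    validateRegime(regime)
    regime
}

#' Validate a parameter regime
#'
#' Checks that ranges are ordered and lie within the [KineticParams-class]
#' invariants (positivity, `g` in (0,1\], modulation factors >= 1,
#' `d` in (0,1)).
#'
#' @param regime a `ParameterRegime`.
#' @return the regime, invisibly; errors on violation.
#' @export
validateRegime <- function(regime) {
    lims <- list(kOn = c(0, Inf), kOff = c(1e-300, Inf),
                 kOpen = c(1e-300, Inf), g = c(1e-300, 1),
                 betaN = c(1, Inf), betaM = c(1, Inf),
                 o = c(1, Inf), c = c(1, Inf), d = c(1e-300, 1 - 1e-12))
    for (nm in names(regime$ranges)) {
        r <- regime$ranges[[nm]]
        if (length(r) != 2L || r[1] > r[2])
            stop("range for '", nm, "' must be ordered c(low, high)")
        if (r[1] < lims[[nm]][1] || r[2] > lims[[nm]][2])
            stop("range for '", nm, "' violates parameter invariants")
    }
    for (nm in names(regime$fixed)) {
        v <- regime$fixed[[nm]]
        if (v < lims[[nm]][1] || v > lims[[nm]][2])
            stop("fixed value for '", nm, "' violates parameter invariants")
    }
    invisible(regime)
}

## Run code with a locally seeded RNG, restoring global state afterwards.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Draw kinetic parameter sets from a regime
#'
#' Reproducible Monte-Carlo sampling: fixed parameters are copied, ranged
#' parameters drawn uniformly on their declared scale (linear or log).
#'
#' @param regime a `ParameterRegime` from [defaultRegime()].
#' @param n number of draws (>= 1).
#' @param seed integer; defaults to the regime's stored seed.
#' @param motifPresent motif flag stamped on every draw.
#' @return list of `n` [KineticParams-class] objects.
#' @examples
#' draws <- sampleParameterSets(defaultRegime(), 3, seed = 7)
#' vapply(draws, function(p) p@g, numeric(1))
#' @export
sampleParameterSets <- function(regime, n, seed = regime$seed,
                                motifPresent = TRUE) {
    stopifnot(inherits(regime, "ParameterRegime"), n >= 1)
    validateRegime(regime)
    n <- as.integer(n)
    .withSeed(seed, {
        draws <- replicate(n, {
            vals <- regime$fixed
            for (nm in names(regime$ranges)) {
                r <- regime$ranges[[nm]]
                vals[[nm]] <- if (identical(unname(regime$scale[nm]), "log"))
                    exp(stats::runif(1, log(r[1]), log(r[2])))
                else stats::runif(1, r[1], r[2])
            }
            do.call(kineticParams, c(vals, list(motifPresent = motifPresent)))
        }, simplify = FALSE)
        draws
    })
}

#' Convert kinetic parameter draws to a data.frame
#'
#' @param params list of [KineticParams-class] objects.
#' @return data.frame with one row per parameter set.
#' @export
paramsToDataFrame <- function(params) {
    if (is(params, "KineticParams")) params <- list(params)
    do.call(rbind, lapply(params, function(p) {
        data.frame(kOn = p@kOn, kOff = p@kOff, g = p@g, betaN = p@betaN,
                   betaM = p@betaM, kOpen = p@kOpen, d = p@d,
                   o = p@o, c = p@c, motifPresent = p@motifPresent)
    }))
}

#' Read / write parameter regimes as JSON
#'
#' Keys are the kinetic parameter names; scalars fix a parameter, two-
#' element arrays declare a range. `scale` and `seed` round-trip too.
#'
#' @param path file path.
#' @param regime a `ParameterRegime`.
#' @return `readRegimeJson` returns a `ParameterRegime`.
#' @export
writeRegimeJson <- function(regime, path) {
    stopifnot(inherits(regime, "ParameterRegime"))
    obj <- c(regime$fixed, regime$ranges,
             list(.scale = as.list(regime$scale), .seed = regime$seed))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeRegimeJson
#' @export
readRegimeJson <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    scale <- if (!is.null(obj$.scale)) unlist(obj$.scale) else NULL
    seed <- if (!is.null(obj$.seed)) as.integer(obj$.seed) else 1L
    obj$.scale <- NULL; obj$.seed <- NULL
    fixed <- obj[vapply(obj, length, integer(1)) == 1L]
    ranges <- obj[vapply(obj, length, integer(1)) == 2L]
    regime <- list(fixed = lapply(fixed, as.numeric),
                   ranges = lapply(ranges, as.numeric),
                   scale = if (is.null(scale))
                       stats::setNames(rep("log", length(ranges)), names(ranges))
                   else scale,
                   seed = seed)
    class(regime) <- "ParameterRegime"
    validateRegime(regime)
    regime
}
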