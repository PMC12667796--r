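## Out-of-equilibrium TF-nucleosome kinetic model: state enumeration,
## column-Laplacian rate matrices, nullspace steady states, accessibility,
## dose-response and two-TF cooperativity.

#' Enumerate the states of the TF-nucleosome chain
#'
#' One TF gives the 4-state chain (closed/open x unbound/bound); two TFs
#' give 8 states (conformation x per-TF occupancy). States are ordered
#' deterministically: all closed states before all open ones, occupancy in
#' binary order with TF 1 as the least-significant flag.
#'
#' @param nTfs number of TFs, 1 or 2.
#' @return data.frame with columns `label`, `conformation` and logical
#'   `bound.<k>` for each TF.
#' @examples
#' enumerateStates(1)$label
#' @export
enumerateStates <- function(nTfs) {
    if (length(nTfs) != 1L || !nTfs %in% c(1, 2))
        stop("unsupported model: nTfs must be 1 or 2")
    nTfs <- as.integer(nTfs)
    occ <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nTfs))[, , drop = FALSE])
    colnames(occ) <- paste0("bound.", seq_len(nTfs))
    states <- do.call(rbind, lapply(c("closed", "open"), function(conf) {
        data.frame(conformation = conf, occ, stringsAsFactors = FALSE)
    }))
    tfTags <- if (nTfs == 1L) "A" else c("A", "B")
    occStr <- apply(states[, paste0("bound.", seq_len(nTfs)), drop = FALSE],
                    1L, function(b) paste(ifelse(b, tfTags, "-"), collapse = ""))
    states <- cbind(label = paste0(states$conformation, "|", occStr), states)
    states$label <- as.character(states$label)
    rownames(states) <- NULL
    states
}

## Off rate of one TF given conformation and the closed+motif convention.
.offRate <- function(p, open, closedMotifRule) {
    if (open) {
        if (p@motifPresent) p@g * p@kOff else p@kOff
    } else {
        if (p@motifPresent) {
            switch(closedMotifRule,
                destabilized = p@betaM * p@g * p@kOff,
                relative_to_nonspecific = p@betaN * p@kOff / p@betaM,
                stop("unknown closedMotifRule"))
        } else {
            p@betaN * p@kOff
        }
    }
}

#' Build the transition-rate matrix of the kinetic model
#'
#' Assembles the column-Laplacian over the enumerated states for 1 or 2
#' TFs. Only single-event transitions carry rate: one TF binds or unbinds,
#' or the conformation flips. Binding into any bound state uses that TF's
#' `kOn` regardless of conformation or motif (diffusion-limited
#' assumption). Unbinding rates: `g*kOff` (open, motif), `kOff` (open, no
#' motif), `betaN*kOff` (closed, no motif) and, under the default
#' convention, `betaM*g*kOff` (closed, motif). Opening from a closed state
#' is `kOpen` times the product of `o` over bound TFs; closing is
#' `(kOpen/d)` divided by the product of `c` over bound TFs (Arrhenius
#' multiplicativity for joint occupancy).
#'
#' @param params a [KineticParams-class] or list of one or two of them.
#'   With two TFs the conformational parameters (`kOpen`, `d`) must agree.
#' @param closedMotifRule convention for the closed-conformation off rate
#'   at a motif: `"destabilized"` (default, `betaM*g*kOff`) or
#'   `"relative_to_nonspecific"` (`betaN*kOff/betaM`, i.e. decreased by
#'   `betaM` relative to the closed no-motif rate).
#' @return A [RateMatrix-class].
#' @examples
#' rm1 <- buildRateMatrix(kineticParams())
#' colSums(rateMatrix(rm1))  # all zero
#' @export
buildRateMatrix <- function(params,
                            closedMotifRule = c("destabilized",
                                                "relative_to_nonspecific")) {
    closedMotifRule <- match.arg(closedMotifRule)
    if (is(params, "KineticParams")) params <- list(params)
    if (!length(params) %in% c(1L, 2L) ||
        !all(vapply(params, is, logical(1), "KineticParams")))
        stop("params must be one or two KineticParams objects")
    for (p in params) validObject(p)
    nTfs <- length(params)
    if (nTfs == 2L) {
        tol <- 1e-12
        if (abs(params[[1]]@kOpen - params[[2]]@kOpen) > tol ||
            abs(params[[1]]@d - params[[2]]@d) > tol)
            stop("inconsistent conformational rates: kOpen and d must agree across TFs")
    }
    states <- enumerateStates(nTfs)
    n <- nrow(states)
    occ <- as.matrix(states[, paste0("bound.", seq_len(nTfs)), drop = FALSE])
    open <- states$conformation == "open"
    kOpen <- params[[1]]@kOpen
    kClose <- kOpen / params[[1]]@d

    Q <- matrix(0, n, n, dimnames = list(states$label, states$label))
    for (j in seq_len(n)) {
        for (i in seq_len(n)) {
            if (i == j) next
            dOcc <- occ[i, ] != occ[j, ]
            dConf <- open[i] != open[j]
            if (sum(dOcc) + dConf != 1L) next  # single-event transitions only
            if (dConf) {
                boundFactors <- vapply(which(occ[j, ]), function(k)
                    c(params[[k]]@o, params[[k]]@c), numeric(2))
                oProd <- if (length(boundFactors)) prod(boundFactors[1, ]) else 1
                cProd <- if (length(boundFactors)) prod(boundFactors[2, ]) else 1
                Q[i, j] <- if (open[i]) kOpen * oProd else kClose / cProd
            } else {
                k <- which(dOcc)
                Q[i, j] <- if (occ[i, k]) params[[k]]@kOn
                           else .offRate(params[[k]], open[j], closedMotifRule)
            }
        }
    }
    diag(Q) <- -colSums(Q)
    new("RateMatrix", matrix = Q, states = states, nTfs = nTfs)
}

#' Steady-state distribution of the chain
#'
#' Solves for the one-dimensional nullspace of the transition-rate matrix
#' by singular-value decomposition (rank tolerance `tol`) and normalizes
#' the null vector to a probability distribution. Errors if the numerical
#' nullspace dimension differs from one (degenerate model).
#'
#' @param rm a [RateMatrix-class].
#' @param tol relative singular-value tolerance for rank determination.
#' @return named numeric vector of steady-state probabilities (sums to 1).
#' @examples
#' p <- steadyState(buildRateMatrix(kineticParams()))
#' sum(p)
#' @export
steadyState <- function(rm, tol = 1e-10) {
    stopifnot(is(rm, "RateMatrix"))
    Q <- rm@matrix
    sv <- svd(Q)
    nullDim <- sum(sv$d < tol * max(sv$d))
    if (nullDim != 1L)
        stop(sprintf("degenerate model: nullspace dimension %d (expected 1)",
                     nullDim))
    v <- sv$v[, ncol(Q)]
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0  # clip numerical noise; null vector is sign-definite
    p <- v / sum(v)
    resid <- max(abs(Q %*% p))
    if (resid > 1e-9 * max(1, max(abs(Q))))
        stop(sprintf("steady-state residual too large: %g", resid))
    names(p) <- rownames(Q)
    p
}

#' Accessibility: probability of the open conformation
#'
#' The sum of steady-state probabilities over open states.
#'
#' @param dist named probability vector from [steadyState()] (names carry
#'   the conformation prefix).
#' @return numeric in \[0, 1\].
#' @export
accessibility <- function(dist) {
    stopifnot(is.numeric(dist), !is.null(names(dist)),
              abs(sum(dist) - 1) < 1e-10, all(dist >= -1e-12))
    sum(dist[startsWith(names(dist), "open")])
}

## Accessibility straight from parameters (internal convenience).
.accessFromParams <- function(params, ...) {
    accessibility(steadyState(buildRateMatrix(params, ...)))
}

#' Kinetic isolation-equivalent log-fold-change
#'
#' Log ratio (natural log) of steady-state accessibility with the motif
#' present over accessibility with the motif absent, all other parameters
#' equal -- the kinetic analogue of the predictor-based isolation score.
#'
#' @param params a [KineticParams-class] describing the motif-present
#'   system.
#' @param ... passed to [buildRateMatrix()].
#' @return numeric log-fold-change.
#' @export
isolationLfcKinetic <- function(params, ...) {
    stopifnot(is(params, "KineticParams"))
    withMotif <- params; withMotif@motifPresent <- TRUE
    noMotif <- params; noMotif@motifPresent <- FALSE
    log(.accessFromParams(withMotif, ...) / .accessFromParams(noMotif, ...))
}

#' Dose-response curve of accessibility versus TF concentration
#'
#' Concentration is absorbed in the association rate, so the curve is
#' traced by sweeping `kOn` of the focal TF over a grid. Optionally a
#' second, cooperating TF is present with fixed parameters (its `kOn`
#' held constant), which raises the accessibility plateau.
#'
#' @param params [KineticParams-class] of the focal TF (its `kOn` is
#'   overridden by the grid).
#' @param konGrid strictly positive, ascending vector of association
#'   rates (s^-1).
#' @param partner optional [KineticParams-class] of a fixed second TF.
#' @param ... passed to [buildRateMatrix()].
#' @return data.frame with columns `kOn` and `accessibility`.
#' @examples
#' doseResponse(kineticParams(o = 20), konGrid = 10^seq(-3, 2))
#' @export
doseResponse <- function(params, konGrid, partner = NULL, ...) {
    stopifnot(is(params, "KineticParams"))
    if (any(!is.finite(konGrid)) || any(konGrid <= 0))
        stop("konGrid values must be strictly positive")
    if (is.unsorted(konGrid, strictly = TRUE))
        stop("konGrid must be strictly ascending")
    acc <- vapply(konGrid, function(k) {
        p <- params; p@kOn <- k
        ps <- if (is.null(partner)) p else list(p, partner)
        .accessFromParams(ps, ...)
    }, numeric(1))
    data.frame(kOn = konGrid, accessibility = acc)
}

#' Two-TF cooperativity from joint versus marginal accessibility
#'
#' Solves the 8-state model under the four sequence scenarios (no motifs;
#' motif A only; motif B only; both motifs), with both TFs always present.
#' Joint effect: `p_AB - p_null`; marginal effect:
#' `(p_A - p_null) + (p_B - p_null)`; cooperativity score:
#' `log(joint / marginal)` (natural log), flagged invalid when either is
#' non-positive.
#'
#' @param paramsA,paramsB [KineticParams-class] for the two TFs (shared
#'   `kOpen` and `d`); their `motifPresent` flags are overridden per
#'   scenario.
#' @param ... passed to [buildRateMatrix()].
#' @return one-row data.frame: `p_null`, `p_A`, `p_B`, `p_AB`, `joint`,
#'   `marginal`, `score`, `valid`.
#' @export
cooperativityKinetic <- function(paramsA, paramsB, ...) {
    stopifnot(is(paramsA, "KineticParams"), is(paramsB, "KineticParams"))
    scen <- function(mA, mB) {
        a <- paramsA; a@motifPresent <- mA
        b <- paramsB; b@motifPresent <- mB
        .accessFromParams(list(a, b), ...)
    }
    pNull <- scen(FALSE, FALSE)
    pA <- scen(TRUE, FALSE)
    pB <- scen(FALSE, TRUE)
    pAB <- scen(TRUE, TRUE)
    joint <- pAB - pNull
    marginal <- (pA - pNull) + (pB - pNull)
    valid <- joint > 0 && marginal > 0
    data.frame(p_null = pNull, p_A = pA, p_B = pB, p_AB = pAB,
               joint = joint, marginal = marginal,
               score = if (valid) log(joint / marginal) else NA_real_,
               valid = valid)
}

#' Detailed-balance residual of a steady state
#'
#' Maximum over state pairs of the absolute net probability flux
#' `|rate(i->j) p_i - rate(j->i) p_j|`. Zero (to numerical precision)
#' exactly when the chain satisfies detailed balance, which for the
#' motif-present single-TF graph holds iff `o * c == betaM` under the
#' default rate conventions; otherwise the system is driven.
#'
#' @param rm a [RateMatrix-class].
#' @param dist its steady-state distribution.
#' @return numeric residual.
#' @export
checkDetailedBalance <- function(rm, dist) {
    stopifnot(is(rm, "RateMatrix"))
    Q <- rm@matrix
    n <- nrow(Q)
    res <- 0
    for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
            ## Q[j, i] is the rate i -> j
            res <- max(res, abs(Q[j, i] * dist[i] - Q[i, j] * dist[j]))
        }
    }
    unname(res)
}

#' Apparent TF binding rate from association constant and concentration
#'
#' Concentration is absorbed into the association rate:
#' `kOn = k'on * [A]`. For Sox2, the in vitro association constant
#' 0.75e-3 s^-1 nM^-1 and nuclear concentrations of 60-120 nM give
#' apparent rates of 0.045-0.09 s^-1, bracketing the fixed simulation
#' default `kOn = 0.1` s^-1.
#'
#' @param assocConst association constant (s^-1 nM^-1).
#' @param concentration TF concentration (nM); vectorized.
#' @return apparent binding rate(s) (s^-1).
#' @examples
#' apparentBindingRate(0.75e-3, c(60, 120))
#' @export
apparentBindingRate <- function(assocConst, concentration) {
    stopifnot(assocConst > 0, all(concentration >= 0))
    assocConst * concentration
}
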