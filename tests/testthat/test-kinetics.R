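test_that("state enumeration is deterministic and sized 2^(nTfs+1)", {
    s1 <- enumerateStates(1)
    expect_identical(s1$label,
                     c("closed|-", "closed|A", "open|-", "open|A"))
    expect_identical(s1$conformation, c("closed", "closed", "open", "open"))
    s2 <- enumerateStates(2)
    expect_equal(nrow(s2), 8L)
    expect_true(all(s2$conformation[1:4] == "closed"))
    expect_false(anyDuplicated(s2$label) > 0)
    expect_error(enumerateStates(3), "unsupported")
    expect_error(enumerateStates(0), "unsupported")
})

test_that("rate matrix entries follow the stated conventions", {
    p <- kineticParams(kOn = 0.2, kOff = 1, g = 0.05, betaN = 5, betaM = 4,
                       kOpen = 0.05, d = 0.01, o = 10, c = 2,
                       motifPresent = FALSE)
    Q <- rateMatrix(buildRateMatrix(p))
    ## closed, no motif: off rate increased five-fold over the open one
    expect_equal(Q["closed|-", "closed|A"], 5)
    expect_equal(Q["open|-", "open|A"], 1)
    ## binding is diffusion-limited: kOn in both conformations
    expect_equal(Q["closed|A", "closed|-"], 0.2)
    expect_equal(Q["open|A", "open|-"], 0.2)
    ## conformational flips: basal when unbound, modulated when bound
    expect_equal(Q["open|-", "closed|-"], 0.05)
    expect_equal(Q["closed|-", "open|-"], 0.05 / 0.01)
    expect_equal(Q["open|A", "closed|A"], 0.05 * 10)
    expect_equal(Q["closed|A", "open|A"], (0.05 / 0.01) / 2)

    pm <- p; pm@motifPresent <- TRUE
    Qm <- rateMatrix(buildRateMatrix(pm))
    expect_equal(Qm["open|-", "open|A"], 0.05 * 1)     # g * kOff
    expect_equal(Qm["closed|-", "closed|A"], 4 * 0.05) # betaM * g * kOff
    ## alternative closed+motif convention
    Qa <- rateMatrix(buildRateMatrix(pm, closedMotifRule = "relative_to_nonspecific"))
    expect_equal(Qa["closed|-", "closed|A"], 5 / 4)    # betaN * kOff / betaM
})

test_that("two-TF matrices multiply bound-TF factors and forbid multi-event jumps", {
    a <- kineticParams(o = 3, c = 2, d = 0.01)
    b <- sharedLocus(a, kineticParams(o = 5, c = 4, d = 0.5))
    rm2 <- buildRateMatrix(list(a, b))
    Q <- rateMatrix(rm2)
    expect_equal(Q["open|AB", "closed|AB"], 0.05 * 3 * 5)
    expect_equal(Q["closed|AB", "open|AB"], (0.05 / 0.01) / (2 * 4))
    ## no simultaneous binding of both TFs or bind+flip
    expect_equal(Q["closed|AB", "closed|--"], 0)
    expect_equal(Q["open|A-", "closed|--"], 0)
    ## Laplacian structure
    expect_lt(max(abs(colSums(Q))), 1e-12 * max(abs(Q)))
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
    ## conformational-rate mismatch is rejected
    expect_error(buildRateMatrix(list(a, kineticParams(d = 0.5))),
                 "inconsistent")
})

test_that("steady state solves the nullspace and matches symmetry limits", {
    ## symmetric toy chain: equal rates everywhere -> uniform distribution
    p <- kineticParams(kOn = 1, kOff = 1, g = 1, betaN = 1, betaM = 1,
                       kOpen = 1, d = 1 - 1e-9, o = 1, c = 1,
                       motifPresent = FALSE)
    ps <- steadyState(buildRateMatrix(p))
    expect_equal(unname(ps), rep(0.25, 4), tolerance = 1e-7)
    expect_equal(sum(ps), 1, tolerance = 1e-12)
    ## residual of the master equation
    rm1 <- buildRateMatrix(kineticParams(g = 0.01, o = 20, c = 2, d = 0.005))
    pr <- steadyState(rm1)
    expect_lt(max(abs(rateMatrix(rm1) %*% pr)), 1e-9)
})

test_that("steady state agrees with long-time ODE integration", {
    regime <- defaultRegime()
    draws <- sampleParameterSets(regime, 12, seed = 3)
    partners <- sampleParameterSets(regime, 12, seed = 103)
    for (i in seq_along(draws)) {
        ps <- if (i %% 2) draws[[i]]
              else list(draws[[i]], sharedLocus(draws[[i]], partners[[i]]))
        rm_ <- buildRateMatrix(ps)
        expect_lt(max(abs(odeSteadyState(rm_) - steadyState(rm_))), 1e-6)
    }
})

test_that("accessibility limits match the closed forms", {
    ## no TF: d / (1 + d)
    for (d in c(0.001, 0.01, 0.049)) {
        p0 <- kineticParams(kOn = 0, d = d)
        expect_equal(accessibility(steadyState(buildRateMatrix(p0))),
                     d / (1 + d), tolerance = 1e-10)
    }
    ## uniform 4-state distribution -> 0.5
    u <- stats::setNames(rep(0.25, 4), enumerateStates(1)$label)
    expect_equal(accessibility(u), 0.5)
    ## saturating kOn: (o c d) / (1 + o c d), independent of g
    o <- 10; cc <- 2; d <- 0.01
    plat <- vapply(c(0.001, 0.01, 0.09), function(g) {
        p <- kineticParams(kOn = 1e6, g = g, o = o, c = cc, d = d)
        accessibility(steadyState(buildRateMatrix(p)))
    }, numeric(1))
    expect_equal(plat, rep((o * cc * d) / (1 + o * cc * d), 3),
                 tolerance = 1e-3)
    expect_lt(max(plat) - min(plat), 1e-3)
})

test_that("kinetic isolation LFC is zero for neutral motifs and monotone in affinity", {
    expect_equal(isolationLfcKinetic(kineticParams(g = 1, betaM = 5, betaN = 5)), 0)
    expect_equal(isolationLfcKinetic(kineticParams(o = 1, c = 1)), 0,
                 tolerance = 1e-12)
    l <- vapply(c(0.09, 0.03, 0.01, 0.003, 0.001), function(g)
        isolationLfcKinetic(kineticParams(g = g, o = 10, c = 2, d = 0.01)),
        numeric(1))
    expect_true(all(diff(l) >= 0))
})

test_that("dose-response curves are monotone, flat for inert TFs, and share plateaus", {
    grid <- 10^seq(-4, 3, length.out = 15)
    flat <- doseResponse(kineticParams(o = 1, c = 1, d = 0.02), grid)
    expect_equal(flat$accessibility, rep(0.02 / 1.02, 15), tolerance = 1e-9)
    dr <- doseResponse(kineticParams(o = 30, c = 3, g = 0.01, d = 0.005), grid)
    expect_true(all(diff(dr$accessibility) >= -1e-12))
    ## same plateau for different affinities
    a1 <- doseResponse(kineticParams(g = 0.001, o = 10, c = 2, d = 0.01), 1e6)
    a2 <- doseResponse(kineticParams(g = 0.09, o = 10, c = 2, d = 0.01), 1e6)
    expect_equal(a1$accessibility, a2$accessibility, tolerance = 1e-3)
    ## a fixed cooperating partner raises the plateau
    base <- kineticParams(g = 0.01, o = 10, c = 2, d = 0.01)
    partner <- sharedLocus(base, kineticParams(kOn = 0.05, g = 0.01, o = 10, c = 2))
    with2 <- doseResponse(base, 1e6, partner = partner)
    expect_gt(with2$accessibility, a1$accessibility)
    expect_error(doseResponse(base, c(-1, 1)), "positive")
    expect_error(doseResponse(base, c(2, 1, 3)), "ascending")
})

test_that("accessibility is monotone in kOn and in affinity over random draws", {
    draws <- sampleParameterSets(defaultRegime(), 10, seed = 17)
    grid <- 10^seq(-3, 2, length.out = 8)
    for (p in draws) {
        acc <- doseResponse(p, grid)$accessibility
        expect_true(all(diff(acc) >= -1e-10))
        accG <- vapply(c(0.09, 0.01, 0.001), function(g) {
            q <- p; q@g <- g
            accessibility(steadyState(buildRateMatrix(q)))
        }, numeric(1))
        expect_true(all(diff(accG) >= -1e-10))  # lower g = higher affinity
    }
})

test_that("two-TF cooperativity factorizes for neutral partners and reduces to one TF", {
    a <- kineticParams(o = 10, c = 2, g = 0.01, d = 0.01)
    neutral <- sharedLocus(a, kineticParams(o = 1, c = 1))
    rec <- cooperativityKinetic(a, neutral)
    expect_equal(rec$p_AB, rec$p_A, tolerance = 1e-10)
    expect_equal(rec$p_B, rec$p_null, tolerance = 1e-10)
    expect_equal(rec$score, 0, tolerance = 1e-9)
    ## symmetric TFs give symmetric marginals
    b <- sharedLocus(a, a)
    recS <- cooperativityKinetic(a, b)
    expect_equal(recS$p_A, recS$p_B, tolerance = 1e-12)
    ## kOn_B -> 0 reduces the 8-state model to the 4-state one
    tiny <- sharedLocus(a, kineticParams(kOn = 1e-9, o = 5, c = 2))
    a2 <- accessibility(steadyState(buildRateMatrix(list(a, tiny))))
    a1 <- accessibility(steadyState(buildRateMatrix(a)))
    expect_lt(abs(a2 - a1), 1e-6)
})

test_that("detailed balance holds exactly when o*c equals betaM", {
    bal <- kineticParams(o = 4, c = 2, betaM = 8, g = 0.02, d = 0.01,
                         motifPresent = TRUE)
    rmB <- buildRateMatrix(bal)
    expect_lt(checkDetailedBalance(rmB, steadyState(rmB)), 1e-10)
    unbal <- kineticParams(o = 4, c = 2, betaM = 5, g = 0.02, d = 0.01)
    rmU <- buildRateMatrix(unbal)
    expect_gt(checkDetailedBalance(rmU, steadyState(rmU)), 1e-6)
    ## two-state subsystem (no TF) is a single edge: always balanced
    p0 <- kineticParams(kOn = 0, d = 0.02)
    rm0 <- buildRateMatrix(p0)
    expect_lt(checkDetailedBalance(rm0, steadyState(rm0)), 1e-12)
})

test_that("parameter sampling respects ranges, defaults and the seed", {
    draws <- sampleParameterSets(defaultRegime(), 50, seed = 7)
    expect_length(draws, 50)
    g <- vapply(draws, function(p) p@g, numeric(1))
    d <- vapply(draws, function(p) p@d, numeric(1))
    bm <- vapply(draws, function(p) p@betaM, numeric(1))
    expect_true(all(vapply(draws, function(p) p@kOn, numeric(1)) == 0.1))
    expect_true(all(vapply(draws, function(p) p@betaN, numeric(1)) == 5))
    expect_true(all(g >= 0.001 & g <= 0.09))
    expect_true(all(d >= 0.001 & d <= 0.05))
    expect_true(all(bm >= 2 & bm <= 10))
    again <- sampleParameterSets(defaultRegime(), 50, seed = 7)
    expect_identical(paramsToDataFrame(draws), paramsToDataFrame(again))
    expect_error(defaultRegime(g = c(0.5, 2)), "invariants")
    expect_error(kineticParams(d = 1.5))
    expect_error(kineticParams(o = 0.5))
})

test_that("parameter regimes round-trip through JSON", {
    reg <- defaultRegime(o = c(2, 50), betaM = 6, seed = 9L)
    path <- withr::local_tempfile(fileext = ".json")
    writeRegimeJson(reg, path)
    back <- readRegimeJson(path)
    expect_equal(back$fixed[order(names(back$fixed))],
                 reg$fixed[order(names(reg$fixed))])
    expect_equal(back$ranges[order(names(back$ranges))],
                 reg$ranges[order(names(reg$ranges))])
    expect_identical(back$seed, 9L)
    d1 <- sampleParameterSets(reg, 5)
    d2 <- sampleParameterSets(back, 5)
    expect_identical(paramsToDataFrame(d1), paramsToDataFrame(d2))
})

test_that("the Sox2 worked example reproduces the apparent binding rates", {
    expect_identical(apparentBindingRate(0.75e-3, 60), 0.045)
    expect_identical(apparentBindingRate(0.75e-3, 120), 0.09)
})
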