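test_that("stability bound is the explicit-Euler limit of the fastest mode", {
    cfg <- wtConfig()
    # max H = 1/251 at the distal cell; fastest rate 2/251 + 0.1
    expect_equal(stabilityBound(cfg$profiles, cfg$params),
                 2 / (2 / 251 + 0.1))
    profiles <- expressionProfiles(fj = rep(0, 3), dsTotal = rep(1, 3),
                                   ftTotal = rep(1, 3))
    params <- modelParameters(nCells = 3, alphaFt = 0, alphaDs = 0,
                              betaFt = 1, betaDs = 1, kOff = 0.1)
    expect_equal(stabilityBound(profiles, params), 2)
    # doubling every rate halves the bound
    double <- modelParameters(nCells = 3, alphaFt = 0, alphaDs = 0,
                              betaFt = 2, betaDs = 2, kOff = 0.2)
    expect_equal(stabilityBound(profiles, double),
                 stabilityBound(profiles, params) / 2)
})

test_that("Euler integration agrees with the exact relaxation", {
    cfg <- wtConfig()
    init <- randomInitialState(cfg$profiles, 42)
    tr <- integratePhospho(init, cfg$profiles, cfg$params,
                           dt = 0.1, tMax = 500, tol = 1e-12)
    expect_true(isConverged(tr))
    # final state within 1e-6 of the closed-form steady state
    ss <- steadyStatePhospho(cfg$profiles, cfg$params)
    k <- length(tr@times)
    expect_lt(max(abs(tr@ftP[k, ] - ftPhos(ss)),
                  abs(tr@dsP[k, ] - dsPhos(ss))), 1e-6)
    # trajectory tracks the analytic solution with O(dt) error
    maxErr <- function(dt) {
        t <- integratePhospho(init, cfg$profiles, cfg$params, dt = dt,
                              tMax = 100, tol = 1e-300)
        e <- 0
        for (j in seq_along(t@times)) {
            ex <- analyticRelaxation(init, cfg$profiles, cfg$params,
                                     t@times[j])
            e <- max(e, abs(t@ftP[j, ] - ftPhos(ex)),
                     abs(t@dsP[j, ] - dsPhos(ex)))
        }
        e
    }
    e1 <- maxErr(0.1)
    e2 <- maxErr(0.05)
    expect_lt(e1, 0.01)
    # first-order convergence: halving dt roughly halves the error
    expect_gt(e2 / e1, 0.35)
    expect_lt(e2 / e1, 0.65)
})

test_that("integration contract: fixed point start, stability refusal", {
    cfg <- wtConfig()
    ss <- steadyStatePhospho(cfg$profiles, cfg$params)
    tr <- integratePhospho(ss, cfg$profiles, cfg$params)
    expect_true(isConverged(tr))
    expect_equal(convergenceTime(tr), 0)
    k <- length(tr@times)
    expect_equal(tr@ftP[k, ], ftPhos(ss), tolerance = 1e-12)
    bad <- 2 * stabilityBound(cfg$profiles, cfg$params)
    expect_error(
        integratePhospho(ss, cfg$profiles, cfg$params, dt = bad),
        "stability violation")
})

test_that("independent adaptive integrator confirms the Euler path", {
    library(deSolve)
    cfg <- wtConfig()
    init <- randomInitialState(cfg$profiles, 5)
    n <- nCells(cfg$profiles)
    rhs <- function(t, y, parms) {
        st <- phosphoState(y[1:n], y[(n + 1):(2 * n)])
        r <- phosphoRates(st, cfg$profiles, cfg$params)
        list(c(r$dFtP, r$dDsP))
    }
    sol <- ode(y = c(ftPhos(init), dsPhos(init)), times = c(0, 50, 200),
               func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
    tr <- integratePhospho(init, cfg$profiles, cfg$params, dt = 0.01,
                           tMax = 200, tol = 1e-300)
    for (tt in c(50, 200)) {
        j <- which.min(abs(tr@times - tt))
        ref <- sol[sol[, "time"] == tt, -1]
        # adaptive solver vs closed form: both tight, fully independent
        ex <- analyticRelaxation(init, cfg$profiles, cfg$params, tt)
        expect_equal(unname(ref[1:n]), ftPhos(ex), tolerance = 1e-8)
        expect_equal(unname(ref[(n + 1):(2 * n)]), dsPhos(ex),
                     tolerance = 1e-8)
        # Euler path agrees within its own O(dt) discretization error
        expect_equal(unname(tr@ftP[j, ]), unname(ref[1:n]),
                     tolerance = 2e-3)
        expect_equal(unname(tr@dsP[j, ]), unname(ref[(n + 1):(2 * n)]),
                     tolerance = 2e-3)
    }
})

test_that("edge kinetics relax onto the algebraic steady state", {
    cfg <- wtConfig()
    ss <- steadyStatePhospho(cfg$profiles, cfg$params)
    # phospho held at steady state: edges from 0 relax to C*
    tr <- integratePhospho(ss, cfg$profiles, cfg$params, tMax = 300,
                           tol = 1e-300)
    edges <- integrateEdges(tr, cfg$params,
                            initialEdges = rep(0, nCells(cfg$profiles) - 1))
    cstar <- edgeTotals(edgeSteadyState(ss, cfg$profiles, cfg$params))
    k <- length(edges@times)
    expect_lt(max(abs(edges@edges[k, ] - cstar)), 1e-6)
    # starting at C* stays at C*
    fixed <- integrateEdges(tr, cfg$params, initialEdges = cstar)
    expect_lt(max(abs(t(fixed@edges) - cstar)), 1e-9)
    # no phosphorylated Ft anywhere: pure exponential dissociation
    zero <- phosphoState(rep(0, 20), rep(0, 20))
    trz <- integratePhospho(zero, cfg$profiles,
                            modelParameters(alphaFt = 0, alphaDs = 0),
                            tMax = 50, tol = 1e-300)
    dec <- integrateEdges(trz, modelParameters(alphaFt = 0, alphaDs = 0),
                          initialEdges = rep(2, 19), dt = 0.1)
    k <- length(dec@times)
    expect_equal(dec@edges[k, ], rep(2 * exp(-0.1 * dec@times[k]), 19),
                 tolerance = 0.05)
})

test_that("steady-state detection finds the earliest stored index", {
    cfg <- wtConfig()
    ss <- steadyStatePhospho(cfg$profiles, cfg$params)
    tr <- integratePhospho(ss, cfg$profiles, cfg$params, settle = 0)
    chk <- checkSteady(tr, tol = 1e-8)
    expect_true(chk$steady)
    expect_equal(chk$index, 1L)
    # truncated far before relaxation: criterion unmet
    init <- randomInitialState(cfg$profiles, 8)
    short <- integratePhospho(init, cfg$profiles, cfg$params, tMax = 1,
                              tol = 1e-300)
    expect_false(checkSteady(short, tol = 1e-8)$steady)
    # default wild-type run reaches tol 1e-8 well inside the horizon
    full <- integratePhospho(init, cfg$profiles, cfg$params)
    chk <- checkSteady(full, tol = 1e-8)
    expect_true(chk$steady)
    expect_lte(chk$time, 500)
})

test_that("conservation bounds hold at every stored Euler state", {
    cfg <- wtConfig()
    for (s in 1:3) {
        init <- randomInitialState(cfg$profiles, s)
        tr <- integratePhospho(init, cfg$profiles, cfg$params, tMax = 200,
                               tol = 1e-300)
        expect_true(all(tr@ftP >= 0) &&
                    all(t(tr@ftP) <= ftTotal(cfg$profiles) + 1e-12))
        expect_true(all(tr@dsP >= 0) &&
                    all(t(tr@dsP) <= dsTotal(cfg$profiles) + 1e-12))
    }
})
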