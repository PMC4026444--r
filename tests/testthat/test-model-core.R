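test_that("Hill coupling evaluates correctly and rejects bad input", {
    expect_equal(hillActivity(250, 1, 250), 0.5)
    expect_equal(hillActivity(0, 1, 250), 0)
    expect_equal(hillActivity(750, 1, 250), 750 / (250 + 750))
    # strictly increasing in the activity
    fj <- seq(0, 1000, by = 10)
    expect_true(all(diff(hillActivity(fj, 2, 250)) > 0))
    # half-saturation lands at K for any coefficient
    for (n in c(1, 2, 4)) expect_equal(hillActivity(123.4, n, 123.4), 0.5)
    expect_error(hillActivity(-1, 1, 250), "non-negative")
    expect_error(hillActivity(NaN, 1, 250), "finite")
    expect_error(hillActivity(1, 0.5, 250), ">= 1")
    expect_error(hillActivity(1, 1, 0), "positive")
})

test_that("unphosphorylated levels follow conservation", {
    fx <- stateFromFtpDsu(ftP = c(0, 0.909091, 0.5),
                          dsU = c(1.5, 1.0, 0.25))
    u <- unphosphorylatedLevels(fx$state, fx$profiles)
    expect_equal(u$ftU, c(1, 0.090909, 0.5))
    expect_equal(u$dsU, c(1.5, 1.0, 0.25))
    # conservation is an identity at any valid state
    cfg <- wtConfig()
    st <- randomState(cfg$profiles, 11)
    u <- unphosphorylatedLevels(st, cfg$profiles)
    expect_equal(u$ftU + ftPhos(st), ftTotal(cfg$profiles))
    expect_equal(u$dsU + dsPhos(st), dsTotal(cfg$profiles))
    # violating the bounds is an error
    bad <- phosphoState(ftP = rep(2, 20), dsP = rep(0, 20))
    expect_error(unphosphorylatedLevels(bad, cfg$profiles), "conservation")
})

test_that("phosphorylation rates match their closed form", {
    # H = 0.5 at fj = K; alpha = 2, ftTotal = 1, ftP = 0 -> rate 1.0
    profiles <- expressionProfiles(fj = rep(250, 3), dsTotal = rep(1, 3),
                                   ftTotal = rep(1, 3))
    params <- modelParameters(nCells = 3, alphaFt = 2, betaFt = 0.1,
                              alphaDs = 2, betaDs = 0.1, hillK = 250)
    r <- phosphoRates(phosphoState(rep(0, 3), rep(0, 3)), profiles, params)
    expect_equal(r$dFtP, rep(1.0, 3))
    # kinase-dead: pure first-order decay
    dead <- modelParameters(nCells = 3, alphaFt = 0, betaFt = 0.1)
    r <- phosphoRates(phosphoState(rep(0.5, 3), rep(0, 3)), profiles, dead)
    expect_equal(r$dFtP, rep(-0.05, 3))
    # the closed-form steady state is a fixed point to machine precision
    cfg <- wtConfig()
    ss <- steadyStatePhospho(cfg$profiles, cfg$params)
    r <- phosphoRates(ss, cfg$profiles, cfg$params)
    expect_lt(max(abs(r$dFtP), abs(r$dDsP)), 1e-15)
    expect_error(
        phosphoRates(phosphoState(rep(0, 5), rep(0, 5)), cfg$profiles,
                     cfg$params),
        "number of cells")
})

test_that("steady state has the a/(a+beta) form and tracks the Fj profile", {
    # H = 0.5, alpha = 2, beta = 0.1 -> x* = 1/1.1
    profiles <- expressionProfiles(fj = rep(250, 3), dsTotal = rep(1, 3),
                                   ftTotal = rep(1, 3))
    params <- modelParameters(nCells = 3)
    ss <- steadyStatePhospho(profiles, params)
    expect_equal(ftPhos(ss), rep(1 / 1.1, 3), tolerance = 1e-12)
    # no kinase, no phosphorylation
    ss0 <- steadyStatePhospho(profiles, modelParameters(nCells = 3,
                                                        alphaFt = 0))
    expect_equal(ftPhos(ss0), rep(0, 3))
    zeroFj <- expressionProfiles(fj = rep(0, 3), dsTotal = rep(1, 3),
                                 ftTotal = rep(1, 3))
    ssz <- steadyStatePhospho(zeroFj, params)
    expect_equal(c(ftPhos(ssz), dsPhos(ssz)), rep(0, 6))
    # monotone along any non-decreasing Fj profile
    cfg <- wtConfig()
    ss <- steadyStatePhospho(cfg$profiles, cfg$params)
    expect_true(all(diff(ftPhos(ss)) > 0))
    expect_true(all(diff(dsPhos(ss) / dsTotal(cfg$profiles)) > 0))
})

test_that("analytic relaxation solves the kinetics exactly", {
    profiles <- expressionProfiles(fj = rep(250, 3), dsTotal = rep(1, 3),
                                   ftTotal = rep(1, 3))
    params <- modelParameters(nCells = 3)
    init <- phosphoState(rep(0, 3), rep(0, 3))
    # identity at t = 0
    expect_equal(analyticRelaxation(init, profiles, params, 0), init)
    # frozen hand value: x* (1 - e^-1.1) at t = 1 with a + beta = 1.1
    at1 <- analyticRelaxation(init, profiles, params, 1)
    expect_equal(ftPhos(at1), rep((1 / 1.1) * (1 - exp(-1.1)), 3),
                 tolerance = 1e-12)
    # asymptotic limit is the steady state
    far <- analyticRelaxation(init, profiles, params, 1e6)
    expect_equal(ftPhos(far), ftPhos(steadyStatePhospho(profiles, params)),
                 tolerance = 1e-12)
    expect_error(analyticRelaxation(init, profiles, params, -1),
                 "non-negative")
    # the closed form satisfies the ODE: centered finite difference
    cfg <- wtConfig()
    init <- randomState(cfg$profiles, 3)
    h <- 1e-5
    for (t in c(0.5, 5, 50)) {
        xm <- analyticRelaxation(init, cfg$profiles, cfg$params, t - h)
        xp <- analyticRelaxation(init, cfg$profiles, cfg$params, t + h)
        xc <- analyticRelaxation(init, cfg$profiles, cfg$params, t)
        r <- phosphoRates(xc, cfg$profiles, cfg$params)
        expect_equal((ftPhos(xp) - ftPhos(xm)) / (2 * h), r$dFtP,
                     tolerance = 1e-7)
        expect_equal((dsPhos(xp) - dsPhos(xm)) / (2 * h), r$dDsP,
                     tolerance = 1e-7)
    }
})

test_that("parameter and profile validity is enforced", {
    expect_error(modelParameters(nCells = 2), "at least one interior")
    expect_error(modelParameters(betaFt = 0), "betaFt")
    expect_error(modelParameters(kOff = 0), "kOff")
    expect_error(modelParameters(hillN = 0.5), "hillN")
    expect_error(modelParameters(mu = -1), "mu")
    expect_error(expressionProfiles(fj = c(-1, 0, 1), dsTotal = rep(1, 3),
                                    ftTotal = rep(1, 3)),
                 "non-negative")
    expect_error(expressionProfiles(fj = rep(1, 3), dsTotal = rep(1, 4),
                                    ftTotal = rep(1, 3)),
                 "equal length")
})
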