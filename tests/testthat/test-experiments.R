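test_that("perturbations rewrite profiles and parameters as specified", {
    cfg <- wtConfig()
    # flatten at the wild-type maximum by default
    flat <- applyPerturbation(cfg$profiles, cfg$params,
                              perturbationSpec("flatten_fj"))
    expect_equal(fjProfile(flat$profiles), rep(1, 20))
    expect_equal(dsTotal(flat$profiles), dsTotal(cfg$profiles))
    flat <- applyPerturbation(cfg$profiles, cfg$params,
                              perturbationSpec("flatten_ds"))
    expect_equal(dsTotal(flat$profiles), rep(1.475, 20))
    both <- applyPerturbation(cfg$profiles, cfg$params,
                              perturbationSpec("flatten_both",
                                               flattenLevel = 2))
    expect_equal(fjProfile(both$profiles), rep(2, 20))
    expect_equal(dsTotal(both$profiles), rep(2, 20))
    # kinase-dead mutants zero one phosphorylation rate, nothing else
    dead <- applyPerturbation(cfg$profiles, cfg$params,
                              perturbationSpec("fj_ft_dead"))
    expect_equal(dead$params@alphaFt, 0)
    expect_equal(dead$params@alphaDs, cfg$params@alphaDs)
    expect_identical(dead$profiles, cfg$profiles)
    # inputs are never mutated
    expect_equal(fjProfile(cfg$profiles), (1:20) / 20)
    expect_equal(cfg$params@alphaFt, 2)
    # overrides and bad input
    ov <- applyPerturbation(cfg$profiles, cfg$params,
                            perturbationSpec("wild_type",
                                             overrides = list(mu = 10)))
    expect_equal(ov$params@mu, 10)
    expect_error(perturbationSpec("flatten_everything"), "kind")
    expect_error(
        applyPerturbation(cfg$profiles, cfg$params,
                          perturbationSpec("wild_type",
                                           overrides = list(aplha_ft = 0))),
        "unknown parameter")
})

test_that("wild type polarizes every interior cell distally", {
    res <- runExperiment("wild_type", seed = 1)
    expect_true(isConverged(res))
    expect_equal(unname(polarityLabels(res)), rep("distal", 18))
    expect_true(all(deltaC(res) > 0))
    # tissue-level heterodimer gradient rises proximal -> distal
    expect_true(all(diff(edgeTotals(res)) > 0))
})

test_that("experiments are deterministic given config and seed", {
    a <- runExperiment("wild_type", seed = 7)
    b <- runExperiment("wild_type", seed = 7)
    expect_identical(ftPhos(a), ftPhos(b))
    expect_identical(deltaC(a), deltaC(b))
})

test_that("kinase-dead and flattening mutants reproduce the phenotypes", {
    # no Ft phosphorylation: heterodimer vanishes, tissue unpolarized
    res <- runExperiment("fj_ft_dead", seed = 2)
    expect_lt(max(edgeTotals(res)), 1e-6)
    expect_equal(unname(polarityLabels(res)), rep("unpolarized", 18))
    # no Ds phosphorylation: polarity intact
    res <- runExperiment("fj_ds_dead", seed = 2)
    expect_equal(unname(polarityLabels(res)), rep("distal", 18))
    # flat Fj kills the Ds-polarity route and distal polarity with it
    res <- runExperiment("flatten_fj", seed = 2)
    expect_lt(max(abs(res@polarity@pDs)), 1e-10)
    expect_false(any(polarityLabels(res) == "distal"))
    # flat Ds alone leaves distal polarity intact
    res <- runExperiment("flatten_ds", seed = 2)
    expect_equal(unname(polarityLabels(res)), rep("distal", 18))
    # both flat: exact loss of asymmetry
    res <- runExperiment("flatten_both", seed = 2)
    expect_lt(max(abs(deltaC(res))), 1e-12)
})

test_that("experiment conclusions are independent of the seed", {
    kinds <- c("wild_type", "flatten_fj", "flatten_ds", "flatten_both",
               "fj_ft_dead", "fj_ds_dead")
    for (kind in kinds) {
        labels <- lapply(c(1, 2, 3), function(s)
            polarityLabels(runExperiment(kind, seed = s)))
        expect_identical(labels[[1]], labels[[2]])
        expect_identical(labels[[1]], labels[[3]])
    }
})

test_that("mu sweep re-weights one steady state consistently", {
    sw <- muSweep(c(0.1, 1, 10), seed = 1)
    expect_equal(nrow(sw), 3 * 18)
    expect_equal(unique(sw$mu), c(0.1, 1, 10))
    # per cell, asymmetry increases with mu (pDs > 0 in wild type)
    for (cell in unique(sw$cell)) {
        dc <- sw$delta_c[sw$cell == cell]
        expect_true(all(diff(dc) > 0))
    }
    # mu = 1 rows equal the wild-type experiment
    wt <- runExperiment("wild_type", seed = 1)
    expect_equal(sw$delta_c[sw$mu == 1], unname(deltaC(wt)))
    # mu = 0: only the (non-positive) Ft-polarity term remains
    sw0 <- muSweep(0, seed = 1)
    expect_true(all(sw0$delta_c <= 0))
    expect_error(muSweep(c(-1, 1)), "non-negative")
})

test_that("sensitivity sweep handles grids, defaults and errors", {
    # empty grid: the single default point, fully distal
    def <- sensitivitySweep(list(), seed = 1)
    expect_equal(nrow(def), 1L)
    expect_equal(def$fraction_distal, 1.0)
    # kinase-dead point reports an unpolarized tissue
    sw <- sensitivitySweep(list(alphaFt = c(0, 2)), seed = 1)
    expect_equal(sw$fraction_distal[sw$value == 0], 0)
    expect_equal(sw$fraction_distal[sw$value == 2], 1)
    # cartesian mode covers the product grid deterministically
    cart <- sensitivitySweep(list(hillN = c(1, 2), kOn = c(0.5, 1)),
                             seed = 1, mode = "cartesian")
    expect_equal(nrow(cart), 4L)
    expect_true(all(cart$fraction_distal == 1))
    expect_error(sensitivitySweep(list(aplha_ft = 1)), "invalid parameter")
})
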