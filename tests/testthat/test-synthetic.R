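test_that("parameter sampling is counter-based and pins printed values", {
    rg <- defaultParameterRanges(11)
    a <- sampleParameterSet(rg, 0)
    b <- sampleParameterSet(rg, 0)
    expect_identical(a, b)
    c2 <- sampleParameterSet(rg, 1)
    expect_false(identical(a[["theta_atp_pmk"]], c2[["theta_atp_pmk"]]))
    expect_identical(a[["k_atp"]], 10)           # pinned for every draw
    expect_identical(c2[["k_atp"]], 10)

    # degenerate range collapses to its value
    rg2 <- parameterRanges(list(x = c(0.2, 0.2), y = c(1, 2)), seed = 5)
    expect_identical(sampleParameterSet(rg2, 3)[["x"]], 0.2)

    # sampling never disturbs the global RNG stream
    set.seed(99); before <- runif(1)
    set.seed(99); invisible(sampleParameterSet(rg, 7)); after <- runif(1)
    expect_identical(before, after)
})

test_that("sampled values respect their ranges", {
    rg <- defaultParameterRanges(4)
    for (d in 0:3) {
        p <- sampleParameterSet(rg, d)
        for (nm in names(rg$ranges)) {
            r <- rg$ranges[[nm]]
            expect_gte(p[[nm]], r[1])
            expect_lte(p[[nm]], r[2])
        }
    }
})

test_that("random HFPN fixtures are valid, sized as asked, and reproducible", {
    net <- randomHFPN(1, 1, 1)
    expect_identical(nrow(validateNetwork(net)), 0L)
    for (seed in c(2, 3)) {
        net <- randomHFPN(seed, 5, 5)
        expect_identical(nrow(places(net)), 5L)
        expect_identical(nrow(transitions(net)), 5L)
        expect_identical(nrow(validateNetwork(net)), 0L)
        expect_equal(randomHFPN(seed, 5, 5), net)
    }
    expect_false(identical(randomHFPN(1, 5, 5), randomHFPN(2, 5, 5)))
})

test_that("ensemble robustness is reproducible and reports sane fractions", {
    rg <- defaultParameterRanges(1)
    res <- ensembleRobustness(1, rg, n_draws = 3,
                              behaviors = "sesquiterpene_monotone",
                              t_end = 120)
    expect_s3_class(res, "EnsembleResult")
    expect_true(all(res$pass_fraction >= 0 & res$pass_fraction <= 1))
    expect_identical(res$n_draws, 3)
    res2 <- ensembleRobustness(1, rg, n_draws = 3,
                               behaviors = "sesquiterpene_monotone",
                               t_end = 120)
    expect_identical(res, res2)

    # a single draw gives a 0/1 fraction, and custom behaviours plug in
    res1 <- ensembleRobustness(2, rg, n_draws = 1,
        behaviors = list(monoterpene_grows = function(tr)
            tail(traceSeries(tr, "monoterpene"), 1) > 1),
        t_end = 120)
    expect_true(res1$pass_fraction[["monoterpene_grows"]] %in% c(0, 1))
    expect_error(ensembleRobustness(1, rg, 1, "no_such_behavior"),
                 "unknown behaviour")
})
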