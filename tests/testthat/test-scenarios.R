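test_that("scenario configurations reproduce the printed settings", {
    p <- defaultParameters(1)

    c1 <- configureScenario(1, p)
    expect_identical(c1$config$switch_states,
                     list(MEV_switch = TRUE, MEP_switch = FALSE,
                          crossSwitch = FALSE))
    expect_identical(c1$config$parameters[["theta_fpp_mk"]], 1e9)

    c3 <- configureScenario(3, p)
    expect_identical(c3$config$parameters[["k_atp"]], 30)
    expect_identical(c3$config$parameters[["theta_mevp_atp"]], 80)
    # the modulator place carries the raised production rate
    pl <- places(c3$net)
    expect_identical(pl$initial[[match("atp_rate_mod", pl$id)]], 30)

    c4 <- configureScenario(4, p)
    expect_identical(c4$config$parameters[["theta_fpp_mk"]], 10)
    expect_identical(p[["theta_fpp_mk"]], 100)  # default untouched

    c5 <- configureScenario(5, p)
    expect_identical(c5$config$switch_states$MEP_switch, TRUE)
    expect_identical(c5$config$switch_states$MEV_switch, FALSE)
    expect_identical(c5$config$parameters[["cross_script"]], 1)
    expect_identical(c5$config$parameters[["t_fos"]], 150)

    expect_error(configureScenario(6, p), "unknown scenario")
})

test_that("scenario configuration is pure", {
    p <- defaultParameters(3)
    a <- configureScenario(2, p)
    b <- configureScenario(2, p)
    expect_equal(a$net, b$net)
    expect_identical(a$config, b$config)
})

test_that("normal production scenarios accumulate their terpene monotonically", {
    p <- defaultParameters(1)
    t1 <- runScenario(1, p, t_end = 200)
    expect_true(isMonotoneNondecreasing(t1, "sesquiterpene", 1e-9))
    expect_gt(tail(traceSeries(t1, "sesquiterpene"), 1), 1)

    t2 <- runScenario(2, p, t_end = 200)
    expect_true(isMonotoneNondecreasing(t2, "monoterpene", 1e-9))
    expect_gt(tail(traceSeries(t2, "monoterpene"), 1), 1)
    # the MEV product stays at its initial value with the pathway gated off
    expect_equal(traceSeries(t2, "sesquiterpene"),
                 rep(1, length(traceTimes(t2))))
})

test_that("crossSwitch stays down until 150 pt and fosmidomycin then accumulates", {
    p <- defaultParameters(1)
    t5 <- runScenario(5, p, t_end = 200)
    t <- traceTimes(t5)
    cs <- traceSeries(t5, "crossSwitch")
    fos <- traceSeries(t5, "fosmidomycin")
    expect_true(all(cs[t < 150] == 0))
    expect_true(all(cs[t >= 151] == 1))
    expect_true(all(fos[t < 150] == 0))
    expect_gt(tail(fos, 1), 0)
    # injection rate ~ k_fos_rate = 2 unit/pt
    expect_equal(tail(fos, 1), 2 * (200 - 150), tolerance = 1)
})

test_that("crosstalk rescues sesquiterpene production under MEV shutdown", {
    p <- defaultParameters(1)
    t5 <- runScenario(5, p, t_end = 400)
    ctrl <- runScenario(5, p, t_end = 400, overrides = list(cross_script = 0))
    expect_gt(terminalFoldChange(t5, ctrl, "sesquiterpene"), 1)
    # cytosolic prenyl intermediates rise from zero only with crosstalk
    expect_gt(tail(traceSeries(t5, "GPP"), 1), 0)
    expect_equal(tail(traceSeries(ctrl, "GPP"), 1), 0)
})
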