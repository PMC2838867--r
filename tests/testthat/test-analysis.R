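mk_trace <- function(t, x, id = "x")
    new("Trace", times = t,
        series = matrix(x, ncol = 1, dimnames = list(NULL, id)),
        meta = list(dt = NA_real_, sample_every = t[2] - t[1]))

test_that("peak counting matches closed-form extrema and filters prominence", {
    t <- seq(0, 4 * pi, by = 0.01)
    expect_identical(countPeaks(mk_trace(t, sin(t)), "x", 0.5), 2L)
    expect_identical(countPeaks(mk_trace(t, rep(3, length(t))), "x", 0.5), 0L)
    # sub-prominence ripples are ignored
    ripple <- 0.1 * sin(t)
    expect_identical(countPeaks(mk_trace(t, ripple), "x", 0.5), 0L)
    expect_error(countPeaks(mk_trace(t, sin(t)), "nope", 1), "unknown species")
})

test_that("peak counting is invariant under shift, and under joint scaling", {
    t <- seq(0, 6 * pi, by = 0.02)
    x <- sin(t) + 0.3 * sin(3.7 * t)
    base <- countPeaks(mk_trace(t, x), "x", 0.4)
    expect_gt(base, 0)
    expect_identical(countPeaks(mk_trace(t, x + 100), "x", 0.4), base)
    expect_identical(countPeaks(mk_trace(t, 5 * x), "x", 5 * 0.4), base)
})

test_that("monotonicity respects the tolerance on successive differences", {
    t <- 0:10
    expect_true(isMonotoneNondecreasing(mk_trace(t, t^2), "x", 0))
    x <- c(0:5, 5 - 2e-6, 6:9)
    expect_false(isMonotoneNondecreasing(mk_trace(0:10, x), "x", 1e-6))
    expect_true(isMonotoneNondecreasing(mk_trace(0:10, x), "x", 1e-5))
})

test_that("deceleration is absent for linear series and found at slope breaks", {
    t <- seq(0, 100, by = 1)
    expect_true(is.na(decelerationTime(mk_trace(t, 2 * t + 5), "x")))
    # slope 1 then 0.1 after t = 50: detected shortly after the breakpoint
    x <- ifelse(t <= 50, t, 50 + 0.1 * (t - 50))
    d <- decelerationTime(mk_trace(t, x), "x", window = 10, drop_fraction = 0.5)
    expect_false(is.na(d))
    expect_gte(d, 50)
    expect_lte(d, 60)
})

test_that("terminal fold change divides terminal values and guards zero", {
    t <- 0:10
    a <- mk_trace(t, seq(0, 30, length.out = 11))
    expect_equal(terminalFoldChange(a, a, "x"), 1.0)
    b <- mk_trace(t, seq(0, 10, length.out = 11))
    expect_equal(terminalFoldChange(a, b, "x"), 3.0)
    z <- mk_trace(t, rep(0, 11))
    expect_error(terminalFoldChange(a, z, "x"), "is 0")
})

test_that("the behaviour report aggregates the analyses", {
    t <- seq(0, 4 * pi, by = 0.01)
    x <- sin(t) + 2
    rep <- behaviorReport(mk_trace(t, x), "x", prominence = 0.5)
    expect_identical(rep$n_peaks, 2L)
    expect_false(rep$monotone)
    expect_equal(rep$terminal_value, tail(x, 1))
})
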