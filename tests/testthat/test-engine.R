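test_that("validateNetwork reports structural violations without raising", {
    net <- hfpn(
        places = list(continuousPlace("A", 1), continuousPlace("B", 1)),
        transitions = list(continuousTransition("T", "0.1 * A")),
        arcs = list(arcSpec("normal", "A", "T"), arcSpec("normal", "T", "B")),
        parameters = numeric())
    expect_identical(nrow(validateNetwork(net)), 0L)

    # place -> place arc
    bad <- net
    bad@arcs <- rbind(bad@arcs,
        data.frame(kind = "normal", source = "A", target = "B",
                   weight = "1", threshold = "0"))
    rep <- validateNetwork(bad)
    expect_identical(nrow(rep), 1L)
    expect_match(rep$message, "non-bipartite")

    # negative continuous initial
    bad <- net
    bad@places$initial[[1]] <- -1
    expect_match(validateNetwork(bad)$message, "negative")

    # dangling endpoint
    bad <- net
    bad@arcs$target[1] <- "ghost"
    expect_true(any(grepl("resolves to nothing", validateNetwork(bad)$message)))

    # speed on a generic transition and discrete kinds are rejected
    bad <- net
    bad@transitions$kind[1] <- "generic"
    expect_true(any(grepl("must not carry a speed", validateNetwork(bad)$message)))
    bad <- net
    bad@places$kind[1] <- "discrete"
    expect_true(any(grepl("unsupported kind", validateNetwork(bad)$message)))
})

test_that("enabling uses >= for test/normal thresholds and strict < for inhibitory", {
    net <- hfpn(
        places = list(continuousPlace("I", 85), continuousPlace("X", 0)),
        transitions = list(continuousTransition("T", "1")),
        arcs = list(arcSpec("inhibitory", "I", "T", threshold = 80),
                    arcSpec("normal", "T", "X")),
        parameters = numeric())
    s <- initialState(net)
    expect_false(isEnabled("T", s, net))                     # 85 >= 80 blocks
    s$marking$I <- 79.9
    expect_true(isEnabled("T", s, net))                      # strictly below
    s$marking$I <- 80
    expect_false(isEnabled("T", s, net))                     # boundary blocks
    expect_equal(effectiveSpeed("T", s, net), 0)

    # a transition with no input arcs is vacuously enabled
    iso <- hfpn(
        places = list(continuousPlace("X", 0)),
        transitions = list(continuousTransition("src", "2")),
        arcs = list(arcSpec("normal", "src", "X")),
        parameters = numeric())
    expect_true(isEnabled("src", initialState(iso), iso))
    expect_equal(effectiveSpeed("src", initialState(iso), iso), 2)
})

test_that("effective speed is the evaluated rate law when enabled", {
    net <- hfpn(
        places = list(continuousPlace("S", 50), continuousPlace("P", 0)),
        transitions = list(continuousTransition("T", "k * S")),
        arcs = list(arcSpec("normal", "S", "T"), arcSpec("normal", "T", "P")),
        parameters = c(k = 0.1))
    expect_equal(effectiveSpeed("T", initialState(net), net), 5)
})

test_that("a step integrates sources, stoichiometric weights and rationing", {
    # source at speed 10, dt 0.1 -> +1.0
    net <- hfpn(
        places = list(continuousPlace("M", 0)),
        transitions = list(continuousTransition("src", "10")),
        arcs = list(arcSpec("normal", "src", "M")),
        parameters = numeric())
    s2 <- stepState(initialState(net), net, 0.1)
    expect_equal(s2$marking$M, 1.0)
    expect_equal(s2$time, 0.1)

    # weight-2 consumption: NADPH-style cofactor drops by 2 v dt
    net <- hfpn(
        places = list(continuousPlace("S", 10), continuousPlace("C", 10),
                      continuousPlace("P", 0)),
        transitions = list(continuousTransition("T", "k * S")),
        arcs = list(arcSpec("normal", "S", "T"),
                    arcSpec("normal", "C", "T", weight = 2),
                    arcSpec("normal", "T", "P")),
        parameters = c(k = 0.5))
    s2 <- stepState(initialState(net), net, 0.1)
    v <- 0.5 * 10
    expect_equal(s2$marking$C, 10 - 2 * v * 0.1)
    expect_equal(s2$marking$S, 10 - v * 0.1)
    expect_equal(s2$marking$P, v * 0.1)

    # starvation rationing: demand 1.0 against marking 0.5 fires at half
    # speed and empties the place without going negative
    net <- hfpn(
        places = list(continuousPlace("S", 0.5), continuousPlace("P", 0)),
        transitions = list(continuousTransition("T", "10")),
        arcs = list(arcSpec("normal", "S", "T"), arcSpec("normal", "T", "P")),
        parameters = numeric())
    s2 <- stepState(initialState(net), net, 0.1)
    expect_equal(s2$marking$S, 0)
    expect_equal(s2$marking$P, 0.5)
})

test_that("rationing is shared across competing consumers and keeps marks nonnegative", {
    net <- hfpn(
        places = list(continuousPlace("S", 1), continuousPlace("P1", 0),
                      continuousPlace("P2", 0)),
        transitions = list(continuousTransition("T1", "30"),
                           continuousTransition("T2", "10")),
        arcs = list(arcSpec("normal", "S", "T1"), arcSpec("normal", "T1", "P1"),
                    arcSpec("normal", "S", "T2"), arcSpec("normal", "T2", "P2")),
        parameters = numeric())
    s2 <- stepState(initialState(net), net, 0.1)
    # total demand 4 against 1 available: both scaled by 1/4
    expect_equal(s2$marking$P1, 0.75)
    expect_equal(s2$marking$P2, 0.25)
    expect_equal(s2$marking$S, 0)
})

test_that("simulation reaches the analytic steady state and decay law", {
    tr <- runSimulation(source_decay_net(k = 10, d = 0.1), t_end = 200,
                        dt = 0.01, sample_every = 1)
    terminal <- tail(traceSeries(tr, "X"), 1)
    expect_lt(abs(terminal - 100) / 100, 0.01)

    d <- 0.1; x0 <- 10; t_end <- 10; dt <- 0.01
    tr <- runSimulation(decay_net(x0 = x0, d = d), t_end = t_end, dt = dt)
    got <- tail(traceSeries(tr, "X"), 1)
    exact <- x0 * exp(-d * t_end)
    euler <- x0 * (1 - d * dt)^(t_end / dt)
    expect_equal(got, euler, tolerance = 1e-12)   # exact discrete solution
    expect_lt(abs(got - exact), x0 * d^2 * dt * t_end)  # first-order bound
})

test_that("t_end = 0 yields a trace holding only the initial marking", {
    tr <- runSimulation(decay_net(), t_end = 0)
    expect_identical(length(traceTimes(tr)), 1L)
    expect_equal(traceSeries(tr, "X"), 10)
})

test_that("divergence past the overflow bound aborts, naming the place", {
    net <- hfpn(
        places = list(continuousPlace("runaway", 1)),
        transitions = list(continuousTransition("auto", "2 * runaway")),
        arcs = list(arcSpec("normal", "auto", "runaway")),
        parameters = numeric())
    expect_error(runSimulation(net, t_end = 200, dt = 0.1,
                               overflow_bound = 1e6),
                 "runaway")
})

test_that("halving dt changes the source/decay trajectory by under 1%", {
    net <- source_decay_net(k = 10, d = 0.1)
    a <- traceSeries(runSimulation(net, 100, dt = 0.1), "X")
    b <- traceSeries(runSimulation(net, 100, dt = 0.05), "X")
    expect_lt(max(abs(a - b)) / max(b), 0.01)
})

test_that("simulation is deterministic", {
    net <- source_decay_net()
    t1 <- runSimulation(net, 50, dt = 0.1)
    t2 <- runSimulation(net, 50, dt = 0.1)
    expect_identical(traceSeries(t1), traceSeries(t2))
})

test_that("generic transitions apply guarded updates at the new time", {
    net <- hfpn(
        places = list(continuousPlace("fos", 0),
                      genericPlace("sw", FALSE)),
        transitions = list(
            genericTransition("arm", when = "time >= 5", set = c(sw = "TRUE")),
            genericTransition("inject", when = "sw & time >= 5",
                              set = c(fos = "fos + 2 * dt"))),
        arcs = list(),
        parameters = numeric())
    tr <- runSimulation(net, 10, dt = 0.1)
    fos <- traceSeries(tr, "fos")
    t <- traceTimes(tr)
    expect_true(all(fos[t < 5] == 0))
    expect_equal(tail(fos, 1), 2 * (10 - 5) + 0.2, tolerance = 0.3)
    expect_equal(traceSeries(tr, "sw")[t >= 6], rep(1, sum(t >= 6)))
})
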