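test_that("the reaction table transcribes both pathways", {
    rt <- reactionTable()
    expect_length(rt, 19)
    orders <- vapply(rt, `[[`, "", "order")
    expect_identical(sum(orders %in% as.character(1:10)), 10L)  # MEV
    expect_identical(sum(orders %in% LETTERS[1:9]), 9L)         # MEP
    cmp <- vapply(rt, `[[`, "", "compartment")
    expect_true(all(cmp[orders %in% as.character(1:10)] == "cytosol"))
    expect_true(all(cmp[orders %in% LETTERS[1:9]] == "plastid"))

    r3 <- rt[[which(orders == "3")]]
    expect_equal(r3$substrates, c(HMG_CoA = 1, NADPH = 2))
    expect_identical(r3$enzyme, "HMGR")

    rG <- rt[[which(orders == "G")]]
    expect_equal(rG$products[c("IPP_2", "DMAPP_2")],
                 c(IPP_2 = 1, DMAPP_2 = 1))

    # reaction 7 is forward-only IPP -> DMAPP
    r7 <- rt[[which(orders == "7")]]
    expect_equal(r7$substrates, c(IPP = 1))
    expect_equal(r7$products, c(DMAPP = 1))
})

test_that("the structural census matches the printed counts", {
    inv <- inventory()
    expect_length(inv$continuous_places, 61)
    expect_length(inv$switches, 3)
    expect_length(inv$modulators, 2)
    expect_length(inv$continuous_transitions, 101)

    net <- buildModel(defaultParameters(1))
    pl <- places(net); tr <- transitions(net)
    expect_identical(nrow(pl), 66L)
    expect_identical(sum(pl$kind == "continuous"), 61L)
    expect_identical(sum(pl$kind == "generic"), 5L)
    expect_identical(sum(tr$kind == "continuous"), 101L)
    expect_identical(nrow(validateNetwork(net)), 0L)

    # 19 enzymes, attached to exactly one reaction each via a test arc
    ar <- arcs(net)
    test_arcs <- ar[ar$kind == "test", ]
    expect_identical(nrow(test_arcs), 19L)
    expect_identical(anyDuplicated(test_arcs$source), 0L)
    enzymes <- test_arcs$source
    expect_true(all(!enzymes %in% ar$source[ar$kind != "test"]))
    expect_true(all(!enzymes %in% ar$target))
})

test_that("structural counts are invariant across parameter sets", {
    for (seed in c(2, 99)) {
        net <- buildModel(defaultParameters(seed))
        expect_identical(nrow(places(net)), 66L)
        expect_identical(sum(transitions(net)$kind == "continuous"), 101L)
        expect_identical(nrow(validateNetwork(net)), 0L)
    }
})

test_that("incomplete parameter sets fail naming the missing key", {
    p <- defaultParameters(1)
    expect_error(buildModel(p[setdiff(names(p), "k_3")]), "k_3")
})

test_that("default parameters pin the printed values and are reproducible", {
    p <- defaultParameters(1)
    expect_identical(p[["k_atp"]], 10)
    expect_identical(p[["theta_fpp_mk"]], 100)
    expect_identical(p[["t_fos"]], 150)
    expect_identical(defaultParameters(7), defaultParameters(7))
    expect_false(identical(defaultParameters(1)[["theta_atp_pmk"]],
                           defaultParameters(2)[["theta_atp_pmk"]]))
})

test_that("without crosstalk arcs and regulatory places the pathways are independent", {
    skip_if_not_installed("igraph")
    net <- buildModel(defaultParameters(1))
    ar <- arcs(net)
    pl <- places(net)
    gen <- pl$id[pl$kind == "generic"]
    cross <- ar$source %in% c("IPP_2", "DMAPP_2") &
        ar$target %in% c("t_r8", "t_r9")
    keep <- ar[!cross & !ar$source %in% gen & !ar$target %in% gen, ]
    nodes <- unique(c(pl$id[pl$kind == "continuous"],
                      transitions(net)$id[transitions(net)$kind == "continuous"]))
    g <- igraph::graph_from_data_frame(keep[, c("source", "target")],
                                       vertices = nodes)
    comps <- igraph::components(g, mode = "weak")
    expect_equal(comps$no, 2)
    memb <- comps$membership
    expect_false(memb[["FPP"]] == memb[["GPP_2"]])   # one per compartment
})

test_that("enzyme places are constant through a full simulation", {
    tr <- runScenario(1, defaultParameters(1), t_end = 60)
    enzymes <- c("AACT", "HMGS", "HMGR", "MK", "PMK", "MVD", "IDI", "GPPS",
                 "FPPS", "STPS", "DXS", "DXR", "MCT", "CMK", "MDS", "HDS",
                 "HDR", "GPPS_2", "MTPS")
    for (e in enzymes)
        expect_true(all(traceSeries(tr, e) == 1), info = e)
})
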