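# Small fixture networks built in code, and an independent ODE reference
# integration used to cross-check the engine on smooth mass-action nets.

# zeroth-order source feeding a first-order sink: analytic steady state k/d
source_decay_net <- function(k = 10, d = 0.1, x0 = 0) {
    hfpn(
        places = list(continuousPlace("X", x0)),
        transitions = list(
            continuousTransition("make", "k"),
            continuousTransition("lose", "d * X")),
        arcs = list(arcSpec("normal", "make", "X"),
                    arcSpec("normal", "X", "lose")),
        parameters = c(k = k, d = d))
}

# pure exponential decay: closed form x0 * exp(-d t)
decay_net <- function(x0 = 10, d = 0.1) {
    hfpn(
        places = list(continuousPlace("X", x0)),
        transitions = list(continuousTransition("lose", "d * X")),
        arcs = list(arcSpec("normal", "X", "lose")),
        parameters = c(d = d))
}

# Independent reference: translate a thresholds-free mass-action HFPN into
# its rate equations and integrate with deSolve::lsoda at tight tolerance.
# Speeds are evaluated by plain eval() on the parsed expression strings in
# a state environment -- none of the engine's compilation machinery.
reference_trajectory <- function(net, times) {
    pl <- places(net); tr <- transitions(net); ar <- arcs(net)
    stopifnot(all(pl$kind == "continuous"), all(tr$kind == "continuous"))
    x0 <- vapply(pl$initial, as.numeric, 0)
    names(x0) <- pl$id
    speeds <- lapply(tr$speed, function(s) parse(text = s)[[1]])
    names(speeds) <- tr$id
    pars <- as.list(parameters(net))
    rhs <- function(t, y, parms) {
        env <- list2env(c(as.list(y), pars))
        v <- vapply(speeds, function(e) eval(e, env), 0)
        dy <- setNames(numeric(length(y)), names(y))
        for (i in seq_len(nrow(ar))) {
            w <- as.numeric(ar$weight[i])
            if (ar$source[i] %in% names(v))        # transition -> place
                dy[ar$target[i]] <- dy[ar$target[i]] + w * v[[ar$source[i]]]
            else                                   # place -> transition
                dy[ar$source[i]] <- dy[ar$source[i]] - w * v[[ar$target[i]]]
        }
        list(dy)
    }
    out <- deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    out[, -1, drop = FALSE]
}
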