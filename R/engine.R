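# HFPNe engine: network construction, validation, threshold-gated enabling,
# and fixed-step continuous firing (explicit Euler on the firing semantics).

#' Build HFPN component specifications
#'
#' Helper constructors for the pieces passed to \code{\link{hfpn}}. Only
#' continuous and generic kinds exist; discrete places/transitions are not
#' part of this engine and are rejected at validation.
#'
#' @param id unique identifier (a valid name usable inside expressions).
#' @param initial initial value: nonnegative numeric for continuous places;
#'   logical or numeric for generic places.
#' @param compartment compartment name (e.g. \code{"cytosol"}).
#' @param label human-readable name.
#' @param speed expression string giving the firing speed in unit/pt.
#' @param when boolean guard expression over generic places, parameters and
#'   \code{time}.
#' @param set named character vector of assignment expressions applied to
#'   places when the guard holds (may reference \code{dt}).
#' @param kind arc kind: \code{"normal"}, \code{"test"} or
#'   \code{"inhibitory"}.
#' @param source,target endpoint ids; exactly one endpoint must be a place
#'   and the other a transition, and test/inhibitory arcs always run place
#'   to transition.
#' @param weight stoichiometric coefficient: a nonnegative number or an
#'   expression string (ignored for test/inhibitory arcs, which never
#'   consume).
#' @param threshold enabling threshold: a number or expression string.
#' @return a list spec consumed by \code{\link{hfpn}}.
#' @name specs
NULL

#' @rdname specs
#' @export
continuousPlace <- function(id, initial = 0, compartment = "default", label = id)
    list(id = id, kind = "continuous", initial = as.numeric(initial),
         compartment = compartment, label = label)

#' @rdname specs
#' @export
genericPlace <- function(id, initial, compartment = "default", label = id)
    list(id = id, kind = "generic", initial = initial,
         compartment = compartment, label = label)

#' @rdname specs
#' @export
continuousTransition <- function(id, speed, compartment = "default")
    list(id = id, kind = "continuous", speed = speed,
         compartment = compartment, update = NULL)

#' @rdname specs
#' @export
genericTransition <- function(id, when, set, compartment = "default")
    list(id = id, kind = "generic", speed = NA_character_,
         compartment = compartment, update = list(when = when, set = set))

#' @rdname specs
#' @export
arcSpec <- function(kind, source, target, weight = 1, threshold = 0)
    list(kind = kind, source = source, target = target,
         weight = as.character(weight), threshold = as.character(threshold))

#' Construct an HFPN network
#'
#' Assembles place, transition and arc specifications (built with the
#' \code{\link{specs}} helpers) and a parameter set into an
#' \code{\linkS4class{HFPN}} object. The object is checked with
#' \code{\link{validateNetwork}}; construction fails on any violation.
#'
#' @param places list of place specs.
#' @param transitions list of transition specs.
#' @param arcs list of arc specs.
#' @param parameters named numeric vector.
#' @param validate raise an error on validation violations (default TRUE).
#' @return an \code{HFPN} object.
#' @examples
#' net <- hfpn(
#'   places = list(continuousPlace("S", 10)),
#'   transitions = list(continuousTransition("decay", "d * S")),
#'   arcs = list(arcSpec("normal", "S", "decay")),
#'   parameters = c(d = 0.1))
#' net
#' @export
hfpn <- function(places, transitions, arcs, parameters = numeric(), validate = TRUE) {
    pl <- data.frame(
        id = vapply(places, `[[`, "", "id"),
        kind = vapply(places, `[[`, "", "kind"),
        compartment = vapply(places, `[[`, "", "compartment"),
        label = vapply(places, `[[`, "", "label"),
        stringsAsFactors = FALSE)
    pl$initial <- lapply(places, `[[`, "initial")
    tr <- data.frame(
        id = vapply(transitions, `[[`, "", "id"),
        kind = vapply(transitions, `[[`, "", "kind"),
        compartment = vapply(transitions, `[[`, "", "compartment"),
        speed = vapply(transitions, function(t) as.character(t$speed %||% NA), ""),
        stringsAsFactors = FALSE)
    tr$update <- lapply(transitions, `[[`, "update")
    ar <- data.frame(
        kind = vapply(arcs, `[[`, "", "kind"),
        source = vapply(arcs, `[[`, "", "source"),
        target = vapply(arcs, `[[`, "", "target"),
        weight = vapply(arcs, `[[`, "", "weight"),
        threshold = vapply(arcs, `[[`, "", "threshold"),
        stringsAsFactors = FALSE)
    if (length(parameters) && (is.null(names(parameters)) || any(names(parameters) == "")))
        stop("parameters must be a fully named numeric vector")
    # names are the only attribute that belongs to a network's parameters
    parameters <- stats::setNames(as.numeric(parameters), names(parameters))
    net <- new("HFPN", places = pl, transitions = tr, arcs = ar,
               parameters = parameters)
    if (validate) {
        rep <- validateNetwork(net)
        if (nrow(rep))
            stop("invalid network:\n  ", paste(rep$message, collapse = "\n  "))
    }
    net
}

#' Initial simulation state of a network
#'
#' @param net an \code{HFPN}.
#' @return a \code{\link{simState}} at time 0 holding every place's
#'   initial value.
#' @export
initialState <- function(net) {
    marking <- net@places$initial
    names(marking) <- net@places$id
    simState(0, marking)
}

#' Replace initial place values
#'
#' Returns a copy of the network with the initial marks of the named places
#' replaced; useful for conservation experiments and custom starting
#' conditions.
#'
#' @param net an \code{HFPN}.
#' @param values named list/vector of new initial values.
#' @return the modified \code{HFPN}.
#' @export
setInitials <- function(net, values) {
    pl <- net@places
    for (nm in names(values)) {
        i <- match(nm, pl$id)
        if (is.na(i)) stop("unknown place: ", nm)
        pl$initial[[i]] <- values[[nm]]
    }
    net@places <- pl
    validObject(net)
    net
}

# Build an HFPN directly from data frames, bypassing the spec helpers
# (used by the reader); still validated by default.
hfpn_from_frames <- function(places, transitions, arcs, parameters, validate = TRUE) {
    net <- new("HFPN", places = places, transitions = transitions,
               arcs = arcs, parameters = parameters)
    if (validate) {
        rep <- validateNetwork(net)
        if (nrow(rep))
            stop("invalid network:\n  ", paste(rep$message, collapse = "\n  "))
    }
    net
}

#' Validate an HFPN network
#'
#' Structural and grammatical checks: unique ids, bipartiteness, resolvable
#' arc endpoints, arc direction rules for test/inhibitory arcs, nonnegative
#' continuous initial marks, nonnegative constant thresholds and weights,
#' kind consistency (continuous transitions carry a speed, generic
#' transitions an update rule, never both), rejection of unsupported kinds,
#' and static identifier resolution for every expression.
#'
#' Always returns a report; an empty report means the network is
#' well-formed. Callers decide whether to raise.
#'
#' @param net an \code{HFPN} object.
#' @return data.frame with columns \code{type} and \code{message}, one row
#'   per violation (zero rows when valid).
#' @export
validateNetwork <- function(net) {
    pl <- net@places; tr <- net@transitions; ar <- net@arcs
    par_names <- names(net@parameters)
    bad <- list()
    add <- function(type, message)
        bad[[length(bad) + 1L]] <<- data.frame(type = type, message = message,
                                               stringsAsFactors = FALSE)

    if (anyDuplicated(pl$id))
        add("duplicate id", paste("duplicate place id:",
            paste(unique(pl$id[duplicated(pl$id)]), collapse = ", ")))
    if (anyDuplicated(tr$id))
        add("duplicate id", paste("duplicate transition id:",
            paste(unique(tr$id[duplicated(tr$id)]), collapse = ", ")))
    clash <- intersect(pl$id, tr$id)
    if (length(clash))
        add("duplicate id", paste("id used for both a place and a transition:",
            paste(clash, collapse = ", ")))

    for (i in seq_len(nrow(pl))) {
        k <- pl$kind[i]
        if (!k %in% c("continuous", "generic")) {
            add("unsupported kind", sprintf(
                "place '%s' has unsupported kind '%s' (only continuous and generic)",
                pl$id[i], k))
            next
        }
        ini <- pl$initial[[i]]
        if (k == "continuous") {
            if (!is.numeric(ini) || length(ini) != 1L || is.na(ini) || ini < 0)
                add("negative initial", sprintf(
                    "continuous place '%s' has negative or non-numeric initial value",
                    pl$id[i]))
        } else if (!(is.logical(ini) || is.numeric(ini)) || length(ini) != 1L)
            add("bad initial", sprintf(
                "generic place '%s' initial must be a boolean or a number", pl$id[i]))
    }

    all_syms <- c(pl$id, par_names)
    for (i in seq_len(nrow(tr))) {
        k <- tr$kind[i]
        if (!k %in% c("continuous", "generic")) {
            add("unsupported kind", sprintf(
                "transition '%s' has unsupported kind '%s' (only continuous and generic)",
                tr$id[i], k))
            next
        }
        upd <- tr$update[[i]]
        if (k == "continuous") {
            if (is.na(tr$speed[i]))
                add("missing speed", sprintf(
                    "continuous transition '%s' has no speed expression", tr$id[i]))
            else {
                msg <- check_expr(tr$speed[i], pl$id, par_names,
                                  sprintf("speed of '%s'", tr$id[i]))
                for (m in msg) add("bad expression", m)
            }
            if (!is.null(upd))
                add("speed/update conflict", sprintf(
                    "continuous transition '%s' must not carry an update rule", tr$id[i]))
        } else {
            if (!is.na(tr$speed[i]))
                add("speed on generic transition", sprintf(
                    "generic transition '%s' must not carry a speed expression", tr$id[i]))
            if (is.null(upd) || is.null(upd$when) || is.null(upd$set) ||
                is.null(names(upd$set)) || any(names(upd$set) == ""))
                add("missing update", sprintf(
                    "generic transition '%s' needs an update rule (when + named set)",
                    tr$id[i]))
            else {
                for (m in check_expr(upd$when, pl$id, par_names,
                                     sprintf("guard of '%s'", tr$id[i])))
                    add("bad expression", m)
                for (j in seq_along(upd$set)) {
                    if (!names(upd$set)[j] %in% pl$id)
                        add("bad update target", sprintf(
                            "update of '%s' targets unknown place '%s'",
                            tr$id[i], names(upd$set)[j]))
                    for (m in check_expr(upd$set[[j]], pl$id, par_names,
                                         sprintf("update of '%s'", tr$id[i])))
                        add("bad expression", m)
                }
            }
        }
    }

    is_place <- function(x) x %in% pl$id
    is_trans <- function(x) x %in% tr$id
    for (i in seq_len(nrow(ar))) {
        s <- ar$source[i]; t <- ar$target[i]
        sp <- is_place(s); st <- is_trans(s)
        tp <- is_place(t); tt <- is_trans(t)
        if (!(sp || st))
            add("dangling arc", sprintf("arc source '%s' resolves to nothing", s))
        if (!(tp || tt))
            add("dangling arc", sprintf("arc target '%s' resolves to nothing", t))
        if ((sp && tp) || (st && tt))
            add("non-bipartite arc", sprintf(
                "non-bipartite arc %s -> %s (both endpoints are %s)", s, t,
                if (sp && tp) "places" else "transitions"))
        if (ar$kind[i] %in% c("test", "inhibitory") && !(sp && tt))
            add("arc direction", sprintf(
                "%s arc %s -> %s must run place -> transition", ar$kind[i], s, t))
        if (!ar$kind[i] %in% c("normal", "test", "inhibitory"))
            add("unsupported kind", sprintf("arc %s -> %s has unknown kind '%s'",
                                            s, t, ar$kind[i]))
        thr <- constant_value(ar$threshold[i])
        if (!is.null(thr) && thr < 0)
            add("negative threshold", sprintf(
                "arc %s -> %s has negative constant threshold %g", s, t, thr))
        else if (is.null(thr))
            for (m in check_expr(ar$threshold[i], pl$id, par_names,
                                 sprintf("threshold of arc %s -> %s", s, t)))
                add("bad expression", m)
        w <- constant_value(ar$weight[i])
        if (!is.null(w) && w < 0)
            add("negative weight", sprintf(
                "arc %s -> %s has negative constant weight %g", s, t, w))
        else if (is.null(w))
            for (m in check_expr(ar$weight[i], pl$id, par_names,
                                 sprintf("weight of arc %s -> %s", s, t)))
                add("bad expression", m)
    }

    if (length(bad)) do.call(rbind, bad)
    else data.frame(type = character(), message = character(),
                    stringsAsFactors = FALSE)
}

# ---- compilation -----------------------------------------------------------

# Compile a validated network into closures and incidence matrices used by
# the stepping loop. Continuous places index into a numeric marking vector
# .m; generic places into a list .g; parameters into .p.
compile_network <- function(net) {
    pl <- net@places; tr <- net@transitions; ar <- net@arcs
    cont <- pl$kind == "continuous"
    cont_ids <- pl$id[cont]
    gen_ids <- pl$id[!cont]
    cont_idx <- as_index(cont_ids)
    gen_idx <- as_index(gen_ids)
    par_idx <- as_index(names(net@parameters))
    m0 <- vapply(pl$initial[cont], as.numeric, 0)
    names(m0) <- cont_ids
    g0 <- pl$initial[!cont]
    names(g0) <- gen_ids

    ct <- which(tr$kind == "continuous")
    gt <- which(tr$kind == "generic")
    ct_ids <- tr$id[ct]
    trans_idx <- as_index(ct_ids)
    n_ct <- length(ct)
    n_cp <- length(cont_ids)

    speedFn <- if (n_ct) compile_exprs(tr$speed[ct], cont_idx, gen_idx, par_idx)
               else function(.m, .g, .p, .t, .dt) numeric(0)

    # enabling: conjunction per transition of nontrivial input-arc conditions
    en_texts <- rep("TRUE", n_ct)
    conds <- vector("list", n_ct)
    in_arc <- ar$target %in% ct_ids
    for (i in which(in_arc)) {
        ti <- trans_idx[[ar$target[i]]]
        src <- ar$source[i]
        thr <- ar$threshold[i]
        cthr <- constant_value(thr)
        if (ar$kind[i] %in% c("normal", "test")) {
            # markings are kept >= 0, so a constant threshold <= 0 is vacuous
            if (!is.null(cthr) && cthr <= 0) next
            cond <- sprintf("(%s >= (%s))", src, thr)
        } else {
            cond <- sprintf("(%s < (%s))", src, thr)
        }
        conds[[ti]] <- c(conds[[ti]], cond)
    }
    for (i in seq_len(n_ct))
        if (!is.null(conds[[i]]))
            en_texts[i] <- paste(conds[[i]], collapse = " & ")
    enabledFn <- compile_exprs(en_texts, cont_idx, gen_idx, par_idx)
    all_enabled <- all(en_texts == "TRUE")

    # incidence: constant-weight normal arcs go into dense matrices; arcs
    # with expression weights are evaluated per step
    Win <- matrix(0, n_cp, n_ct)   # consumption: place x transition
    Wout <- matrix(0, n_cp, n_ct)  # production
    dyn <- list()                  # dynamic-weight arcs
    for (i in which(ar$kind == "normal")) {
        s <- ar$source[i]; t <- ar$target[i]
        if (!is.null(cont_idx[[s]]) && !is.null(trans_idx[[t]])) {
            p <- cont_idx[[s]]; k <- trans_idx[[t]]; dir <- "in"
        } else if (!is.null(trans_idx[[s]]) && !is.null(cont_idx[[t]])) {
            p <- cont_idx[[t]]; k <- trans_idx[[s]]; dir <- "out"
        } else next  # arcs touching generic places or generic transitions
        w <- constant_value(ar$weight[i])
        if (!is.null(w)) {
            if (dir == "in") Win[p, k] <- Win[p, k] + w
            else Wout[p, k] <- Wout[p, k] + w
        } else {
            dyn[[length(dyn) + 1L]] <- list(
                place = p, trans = k, dir = dir,
                weightFn = compile_expr1(ar$weight[i], cont_idx, gen_idx, par_idx))
        }
    }
    Cpat <- Win > 0  # static consumption pattern for the starvation guard

    # generic transitions: guard + ordered assignments
    gts <- lapply(gt, function(i) {
        upd <- tr$update[[i]]
        sets <- lapply(seq_along(upd$set), function(j) {
            tgt <- names(upd$set)[j]
            list(cont = !is.null(cont_idx[[tgt]]),
                 idx = cont_idx[[tgt]] %||% gen_idx[[tgt]],
                 fn = compile_expr1(upd$set[[j]], cont_idx, gen_idx, par_idx))
        })
        list(id = tr$id[i],
             whenFn = compile_expr1(upd$when, cont_idx, gen_idx, par_idx),
             sets = sets)
    })

    list(cont_ids = cont_ids, gen_ids = gen_ids, m0 = m0, g0 = g0,
         ct_ids = ct_ids, p = unname(net@parameters),
         speedFn = speedFn, enabledFn = enabledFn, all_enabled = all_enabled,
         Win = Win, Wout = Wout, Cpat = Cpat, dyn = dyn, gts = gts,
         n_ct = n_ct, n_cp = n_cp)
}

# One Euler step on compiled state; returns list(m, g). Speeds are computed
# simultaneously from the pre-step marking; the starvation guard rations, in
# a single simultaneous pass, every transition drawing on a place whose total
# demanded consumption this step exceeds its marking (each such transition
# fires at its speed times the minimum availability fraction over the places
# it consumes, so no marking can go negative); generic updates apply after
# the continuous update, in declaration order, at the new time.
step_compiled <- function(cmp, m, g, t, dt) {
    v <- cmp$speedFn(m, g, cmp$p, t, dt)
    if (anyNA(v) || any(!is.finite(v)))
        stop("speed expression evaluated to a non-finite value at t = ", t)
    if (any(v < 0))
        stop("negative speed for transition '",
             cmp$ct_ids[which(v < 0)[1L]], "' at t = ", t)
    if (!cmp$all_enabled) {
        en <- cmp$enabledFn(m, g, cmp$p, t, dt)
        v <- v * en
    }
    # demand per place
    demand <- as.vector(cmp$Win %*% v) * dt
    dynw <- NULL
    if (length(cmp$dyn)) {
        dynw <- vapply(cmp$dyn, function(d) {
            w <- d$weightFn(m, g, cmp$p, t, dt)
            if (d$dir == "in" && w > 0)
                demand[d$place] <<- demand[d$place] + w * v[d$trans] * dt
            w
        }, 0)
    }
    over <- which(demand > m)
    if (length(over)) {
        scale <- rep(1, cmp$n_ct)
        for (p in over) {
            f <- m[p] / demand[p]  # demand > m >= 0, so demand > 0
            cons <- cmp$Cpat[p, ]
            scale[cons] <- pmin(scale[cons], f)
        }
        if (length(cmp$dyn))
            for (j in seq_along(cmp$dyn)) {
                d <- cmp$dyn[[j]]
                if (d$dir == "in" && dynw[j] > 0 && demand[d$place] > m[d$place])
                    scale[d$trans] <- min(scale[d$trans],
                                          m[d$place] / demand[d$place])
            }
        v <- v * scale
    }
    dm <- as.vector(cmp$Wout %*% v - cmp$Win %*% v) * dt
    if (length(cmp$dyn))
        for (j in seq_along(cmp$dyn)) {
            d <- cmp$dyn[[j]]
            dd <- dynw[j] * v[d$trans] * dt
            if (d$dir == "in") dm[d$place] <- dm[d$place] - dd
            else dm[d$place] <- dm[d$place] + dd
        }
    m <- m + as.vector(dm)
    # floating-point dust from an exactly exhausted place
    m[m < 0] <- 0
    t2 <- t + dt
    for (gtr in cmp$gts) {
        if (isTRUE(as.logical(gtr$whenFn(m, g, cmp$p, t2, dt)))) {
            for (s in gtr$sets) {
                val <- s$fn(m, g, cmp$p, t2, dt)
                if (s$cont) {
                    if (!is.finite(val) || val < 0)
                        stop("generic update of '", gtr$id,
                             "' would set a continuous place negative or non-finite")
                    m[s$idx] <- val
                } else g[[s$idx]] <- val
            }
        }
    }
    list(m = m, g = g)
}

state_from_compiled <- function(cmp, m, g, t) {
    marking <- c(as.list(m), g)
    simState(t, marking[c(cmp$cont_ids, cmp$gen_ids)])
}

marking_to_mg <- function(cmp, state) {
    mk <- state$marking
    miss <- setdiff(c(cmp$cont_ids, cmp$gen_ids), names(mk))
    if (length(miss))
        stop("state marking is missing place(s): ", paste(miss, collapse = ", "))
    m <- vapply(mk[cmp$cont_ids], as.numeric, 0)
    names(m) <- cmp$cont_ids
    g <- mk[cmp$gen_ids]
    list(m = m, g = g)
}

#' Transition enabling under threshold semantics
#'
#' A continuous transition is enabled iff every input normal/test arc's
#' source marking is at or above the arc threshold, and every inhibitory
#' arc's source marking is strictly below its threshold.
#'
#' @param transition a continuous transition id.
#' @param state a \code{\link{simState}}.
#' @param net the \code{HFPN} network.
#' @return logical.
#' @export
isEnabled <- function(transition, state, net) {
    tr <- net@transitions
    i <- match(transition, tr$id)
    if (is.na(i)) stop("unknown transition: ", transition)
    if (tr$kind[i] != "continuous")
        stop("enabling is defined for continuous transitions only")
    ar <- net@arcs
    mk <- state$marking
    for (j in which(ar$target == transition)) {
        src <- ar$source[j]
        if (!src %in% names(mk)) stop("unresolvable place id: ", src)
        val <- as.numeric(mk[[src]])
        thr <- evaluateExpression(ar$threshold[j], state, net@parameters)
        if (ar$kind[j] %in% c("normal", "test")) {
            if (val < thr) return(FALSE)
        } else if (val >= thr) return(FALSE)
    }
    TRUE
}

#' Effective speed of a continuous transition
#'
#' Zero when the transition is not enabled (see \code{\link{isEnabled}});
#' otherwise the speed expression evaluated on the current marking and
#' parameters. Never negative.
#'
#' @inheritParams isEnabled
#' @return nonnegative numeric, unit/pt.
#' @export
effectiveSpeed <- function(transition, state, net) {
    tr <- net@transitions
    i <- match(transition, tr$id)
    if (is.na(i)) stop("unknown transition: ", transition)
    if (tr$kind[i] != "continuous")
        stop("effective speed is defined for continuous transitions only")
    if (!isEnabled(transition, state, net)) return(0)
    v <- evaluateExpression(tr$speed[i], state, net@parameters)
    if (v < 0) stop("negative speed for transition '", transition, "'")
    v
}

#' Advance a simulation state by one step
#'
#' One explicit fixed-step update of the continuous firing semantics:
#' all effective speeds are computed simultaneously from the pre-step
#' marking; each place changes by dt times (inflow minus outflow); a
#' single-pass starvation guard rations any transition whose demanded
#' consumption from some place would exceed that place's marking this step
#' (the transition fires at its speed scaled by the smallest
#' availability fraction marking/demand over the places it consumes, so a
#' nearly empty place throttles its consumers instead of going negative);
#' generic transition updates whose guards hold then apply at the new time,
#' in declaration order. Continuous markings remain nonnegative.
#'
#' @param state a \code{\link{simState}} covering every place of \code{net}.
#' @param net the \code{HFPN} network.
#' @param dt step size in pt, > 0.
#' @return the new \code{SimState}.
#' @export
stepState <- function(state, net, dt) {
    stopifnot(dt > 0)
    cmp <- compile_network(net)
    mg <- marking_to_mg(cmp, state)
    out <- step_compiled(cmp, mg$m, mg$g, state$time, dt)
    state_from_compiled(cmp, out$m, out$g, state$time + dt)
}

#' Simulate an HFPN network
#'
#' Fixed-step simulation from the network's initial marking to
#' \code{t_end}, recording every place (generic booleans as 0/1) every
#' \code{sample_every} pt, including t = 0 and t = t_end. Deterministic:
#' identical inputs give bit-identical traces.
#'
#' @param net a valid \code{HFPN}.
#' @param t_end simulation horizon in pt (t_end = 0 yields a trace holding
#'   only the initial marking).
#' @param dt integration step in pt; default 0.1.
#' @param sample_every sampling interval in pt (a multiple of dt);
#'   default 1.
#' @param overflow_bound divergence guard: the run aborts, naming the
#'   offending place, if any marking exceeds this bound at a sampling
#'   instant. Default 1e9.
#' @param meta extra metadata stored in the trace (scenario id, seed, ...).
#' @return a \code{\linkS4class{Trace}}.
#' @examples
#' net <- hfpn(
#'   places = list(continuousPlace("X", 0)),
#'   transitions = list(
#'     continuousTransition("make", "k"),
#'     continuousTransition("lose", "d * X")),
#'   arcs = list(arcSpec("normal", "make", "X"),
#'               arcSpec("normal", "X", "lose")),
#'   parameters = c(k = 10, d = 0.1))
#' tr <- runSimulation(net, t_end = 50, dt = 0.01)
#' tail(traceSeries(tr, "X"), 1)  # approaches k/d = 100
#' @export
runSimulation <- function(net, t_end, dt = 0.1, sample_every = 1,
                          overflow_bound = 1e9, meta = list()) {
    stopifnot(t_end >= 0)
    cmp <- compile_network(net)
    all_ids <- c(cmp$cont_ids, cmp$gen_ids)
    record <- function(m, g)
        unname(c(m, vapply(g, as.numeric, 0)))
    if (t_end == 0) {
        series <- matrix(record(cmp$m0, cmp$g0), nrow = 1,
                         dimnames = list(NULL, all_ids))
        return(new("Trace", times = 0, series = series,
                   meta = c(list(dt = dt, sample_every = sample_every), meta)))
    }
    stopifnot(dt > 0, dt <= sample_every, sample_every <= t_end)
    n_steps <- round(t_end / dt)
    if (abs(n_steps * dt - t_end) > 1e-9 * max(1, t_end))
        stop("t_end must be an integer multiple of dt")
    k_sample <- round(sample_every / dt)
    if (abs(k_sample * dt - sample_every) > 1e-9)
        stop("sample_every must be an integer multiple of dt")
    m <- cmp$m0; g <- cmp$g0
    keep <- unique(c(seq(0L, n_steps, by = k_sample), n_steps))
    out <- matrix(NA_real_, length(keep), length(all_ids),
                  dimnames = list(NULL, all_ids))
    times <- keep * dt
    out[1L, ] <- record(m, g)
    row <- 1L
    for (s in seq_len(n_steps)) {
        res <- step_compiled(cmp, m, g, (s - 1L) * dt, dt)
        m <- res$m; g <- res$g
        if (s == keep[row + 1L]) {
            row <- row + 1L
            out[row, ] <- record(m, g)
            mx <- max(m)
            if (mx > overflow_bound)
                stop("divergence: place '", cmp$cont_ids[which.max(m)],
                     "' exceeded the overflow bound ", overflow_bound,
                     " at t = ", s * dt)
        }
    }
    new("Trace", times = times, series = out,
        meta = c(list(dt = dt, sample_every = sample_every), meta))
}
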