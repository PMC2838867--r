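# Restricted expression grammar for speeds, thresholds, weights and guards.
#
# Allowed: numeric/logical literals, parameter names, place references, the
# reserved symbols `time` and `dt`, arithmetic (+ - * /), min/max, ifelse
# guards, comparisons and boolean connectives. Expressions are stored as
# strings, parsed once, checked against the whitelist, and compiled into
# closures over (continuous marking vector, generic value list, parameter
# vector, time, dt) so that a simulation step costs a handful of closure
# calls rather than repeated parsing.

.ALLOWED_CALLS <- c("+", "-", "*", "/", "(", "min", "max", "ifelse",
                    ">", ">=", "<", "<=", "==", "!=", "!",
                    "&", "|", "&&", "||")
.RESERVED <- c("time", "dt", "TRUE", "FALSE", "T", "F")

parse_expr <- function(text) {
    p <- tryCatch(parse(text = text, keep.source = FALSE),
                  error = function(e) stop("cannot parse expression '", text,
                                           "': ", conditionMessage(e), call. = FALSE))
    if (length(p) != 1L)
        stop("expression must be a single statement: '", text, "'", call. = FALSE)
    p[[1L]]
}

# All symbols referenced by an expression (excluding reserved words).
expr_symbols <- function(e) {
    syms <- character()
    walk <- function(x) {
        if (is.symbol(x)) {
            s <- as.character(x)
            if (!s %in% .RESERVED) syms[[length(syms) + 1L]] <<- s
        } else if (is.call(x)) {
            fn <- as.character(x[[1L]])
            if (!fn %in% .ALLOWED_CALLS)
                stop("operator or function '", fn,
                     "' is outside the expression grammar", call. = FALSE)
            for (i in seq_along(x)[-1L]) walk(x[[i]])
        } else if (!(is.numeric(x) || is.logical(x))) {
            stop("literal of unsupported type in expression", call. = FALSE)
        }
    }
    walk(e)
    unique(syms)
}

# Static check: every symbol must resolve to a place, a parameter, or a
# reserved word. Returns character() when fine, messages otherwise.
check_expr <- function(text, place_ids, param_names, what = "expression") {
    res <- tryCatch(expr_symbols(parse_expr(text)), error = function(e) e)
    if (inherits(res, "error"))
        return(paste0(what, ": ", conditionMessage(res)))
    unknown <- setdiff(res, c(place_ids, param_names))
    if (length(unknown))
        paste0(what, ": unknown identifier(s) ", paste(unknown, collapse = ", "))
    else character()
}

# Rewrite symbols into indexed accesses: continuous place -> .m[i],
# generic place -> .g[[i]], parameter -> .p[[j]], time -> .t, dt -> .dt.
rewrite_expr <- function(e, cont_idx, gen_idx, par_idx) {
    walk <- function(x) {
        if (is.symbol(x)) {
            s <- as.character(x)
            if (s %in% c("TRUE", "FALSE", "T", "F")) return(x)
            if (s == "time") return(quote(.t))
            if (s == "dt") return(quote(.dt))
            i <- cont_idx[[s]]
            if (!is.null(i)) return(bquote(.m[.(i)]))
            i <- gen_idx[[s]]
            if (!is.null(i)) return(bquote(.g[[.(i)]]))
            i <- par_idx[[s]]
            if (!is.null(i)) return(bquote(.p[[.(i)]]))
            stop("unknown identifier '", s, "' in expression", call. = FALSE)
        }
        if (is.call(x)) {
            for (i in seq_along(x)[-1L]) x[[i]] <- walk(x[[i]])
            x
        } else x
    }
    walk(e)
}

# Compile a vector of expression strings into one closure returning c(...).
compile_exprs <- function(texts, cont_idx, gen_idx, par_idx) {
    exprs <- lapply(texts, function(tx)
        rewrite_expr(parse_expr(tx), cont_idx, gen_idx, par_idx))
    body <- as.call(c(quote(c), exprs))
    f <- function(.m, .g, .p, .t, .dt) NULL
    body(f) <- body
    environment(f) <- baseenv()
    f
}

compile_expr1 <- function(text, cont_idx, gen_idx, par_idx) {
    e <- rewrite_expr(parse_expr(text), cont_idx, gen_idx, par_idx)
    f <- function(.m, .g, .p, .t, .dt) NULL
    body(f) <- e
    environment(f) <- baseenv()
    f
}

# True when the expression is a bare nonnegative numeric constant.
constant_value <- function(text) {
    e <- tryCatch(parse_expr(text), error = function(e) NULL)
    if (is.null(e)) return(NULL)
    if (is.numeric(e)) return(as.numeric(e))
    # allow unary minus on a literal so "-1" is recognised as constant
    if (is.call(e) && identical(e[[1L]], as.symbol("-")) &&
        length(e) == 2L && is.numeric(e[[2L]]))
        return(-as.numeric(e[[2L]]))
    NULL
}

#' Evaluate an expression in the restricted grammar
#'
#' Evaluates a speed/threshold/guard expression against a simulation state
#' and a parameter set. The grammar allows numeric and logical literals,
#' parameter names, place references, \code{+ - * /}, \code{min}/\code{max},
#' \code{ifelse} guards, comparisons, boolean connectives, and the reserved
#' symbols \code{time} and \code{dt}. Evaluation is pure: identical inputs
#' give identical output.
#'
#' @param expr expression string.
#' @param state simulation state as returned by \code{\link{simState}}: a
#'   list with elements \code{time} (pt) and \code{marking} (named list of
#'   place values).
#' @param params named numeric vector of parameters.
#' @param dt step size bound to the reserved symbol \code{dt} (default 0).
#' @return the expression value (numeric or logical scalar).
#' @examples
#' s <- simState(0, list(MEVP = 40))
#' evaluateExpression("0.1 * MEVP", s, c(k = 1))  # 4
#' @export
evaluateExpression <- function(expr, state, params = numeric(), dt = 0) {
    marking <- state$marking
    ids <- names(marking)
    is_num <- vapply(marking, function(v) is.numeric(v) && !is.logical(v), logical(1))
    cont_ids <- ids[is_num]
    gen_ids <- ids[!is_num]
    cont_idx <- as_index(cont_ids); gen_idx <- as_index(gen_ids)
    par_idx <- as_index(names(params))
    syms <- expr_symbols(parse_expr(expr))
    unknown <- setdiff(syms, c(ids, names(params)))
    if (length(unknown))
        stop("unknown identifier(s) in expression: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    f <- compile_expr1(expr, cont_idx, gen_idx, par_idx)
    v <- f(unlist(marking[cont_ids], use.names = FALSE),
           marking[gen_ids], unname(params), state$time, dt)
    if (is.numeric(v) && !all(is.finite(v)))
        stop("expression '", expr, "' evaluated to a non-finite value ",
             "(division by zero?)", call. = FALSE)
    v
}

as_index <- function(ids) {
    idx <- as.list(seq_along(ids))
    names(idx) <- ids
    idx
}

#' Construct a simulation state
#'
#' A simulation state is the current Petri net time together with the
#' marking of every place: nonnegative reals for continuous places,
#' booleans or numbers for generic places.
#'
#' @param time nonnegative time in pt.
#' @param marking named list of place values.
#' @return a list with class \code{"SimState"}.
#' @export
simState <- function(time, marking) {
    stopifnot(is.numeric(time), time >= 0, is.list(marking))
    if (is.null(names(marking)) || anyDuplicated(names(marking)))
        stop("marking must be a uniquely named list")
    structure(list(time = time, marking = marking), class = "SimState")
}
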