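#' @import methods
NULL

#' HFPN: a hybrid functional Petri net
#'
#' An \code{HFPN} object holds the complete bipartite network: places
#' (continuous places carry nonnegative real marks, generic places carry
#' boolean or numeric values), transitions (continuous transitions fire at a
#' rate given by a speed expression; generic transitions apply guarded
#' assignments), arcs (normal, test, inhibitory) and a named parameter set.
#'
#' Slots are plain data frames so that networks serialise exactly and can be
#' inspected with ordinary data-frame tools; use the accessors
#' \code{\link{places}}, \code{\link{transitions}}, \code{\link{arcs}} and
#' \code{\link{parameters}} rather than \code{@} access.
#'
#' @slot places data.frame with columns \code{id}, \code{kind}
#'   (\code{"continuous"} or \code{"generic"}), \code{compartment},
#'   \code{label}, and a list column \code{initial} (numeric for continuous
#'   places, logical or numeric for generic places).
#' @slot transitions data.frame with columns \code{id}, \code{kind},
#'   \code{compartment}, \code{speed} (expression string; \code{NA} for
#'   generic transitions) and a list column \code{update} (\code{NULL} for
#'   continuous transitions; for generic transitions a list with elements
#'   \code{when}, a boolean guard expression, and \code{set}, a named
#'   character vector of assignment expressions).
#' @slot arcs data.frame with columns \code{kind} (\code{"normal"},
#'   \code{"test"}, \code{"inhibitory"}), \code{source}, \code{target},
#'   \code{weight} (expression string, usually a constant; ignored for test
#'   and inhibitory arcs) and \code{threshold} (expression string, default
#'   \code{"0"}).
#' @slot parameters named numeric vector of rate constants and thresholds.
#'
#' @seealso \code{\link{hfpn}}, \code{\link{validateNetwork}},
#'   \code{\link{simulate}}
#' @export
setClass("HFPN", slots = c(
    places      = "data.frame",
    transitions = "data.frame",
    arcs        = "data.frame",
    parameters  = "numeric"
))

#' Trace: a sampled simulation trajectory
#'
#' Time-indexed record of every place's value at a fixed sampling interval,
#' in Petri net time (pt). Generic boolean places are recorded as 0/1.
#'
#' @slot times strictly increasing numeric vector of sampled pt values.
#' @slot series numeric matrix, one row per sampled time, one column per
#'   place, columns in network declaration order.
#' @slot meta list with at least \code{dt}, \code{sample_every}, and
#'   optionally \code{scenario}, \code{seed} and the full run configuration.
#' @seealso \code{\link{simulate}}, \code{\link{traceSeries}}
#' @export
setClass("Trace", slots = c(
    times  = "numeric",
    series = "matrix",
    meta   = "list"
))

# Validity checks the container shape only; the deep structural and
# grammatical checks live in validateNetwork(), which always returns a
# report so callers can inspect broken networks.
setValidity("HFPN", function(object) {
    msg <- character()
    need <- function(df, cols, what) {
        miss <- setdiff(cols, names(df))
        if (length(miss))
            msg <<- c(msg, paste0(what, " missing column(s): ",
                                  paste(miss, collapse = ", ")))
    }
    need(object@places, c("id", "kind", "compartment", "initial"), "places")
    need(object@transitions, c("id", "kind", "compartment", "speed", "update"),
         "transitions")
    need(object@arcs, c("kind", "source", "target", "weight", "threshold"),
         "arcs")
    if (length(object@parameters) &&
        length(names(object@parameters)) != length(object@parameters))
        msg <- c(msg, "parameters must be fully named")
    if (length(msg)) msg else TRUE
})

setValidity("Trace", function(object) {
    msg <- character()
    if (length(object@times) != nrow(object@series))
        msg <- c(msg, "times and series rows differ in length")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (length(msg)) msg else TRUE
})

setMethod("show", "HFPN", function(object) {
    pl <- object@places; tr <- object@transitions
    cat(sprintf("HFPN network: %d places (%d continuous, %d generic), %d transitions (%d continuous, %d generic), %d arcs\n",
        nrow(pl), sum(pl$kind == "continuous"), sum(pl$kind == "generic"),
        nrow(tr), sum(tr$kind == "continuous"), sum(tr$kind == "generic"),
        nrow(object@arcs)))
    cmp <- unique(pl$compartment)
    cat("compartments:", paste(cmp, collapse = ", "), "\n")
    cat("parameters:", length(object@parameters), "named values\n")
    invisible(object)
})

setMethod("show", "Trace", function(object) {
    cat(sprintf("Trace: %d samples over [%g, %g] pt, %d species (dt = %s, sample_every = %s)\n",
        length(object@times), min(object@times), max(object@times),
        ncol(object@series),
        format(object@meta$dt %||% NA), format(object@meta$sample_every %||% NA)))
    if (!is.null(object@meta$scenario))
        cat("scenario:", object@meta$scenario, "\n")
    invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accessors for HFPN and Trace objects
#'
#' @param x an \code{HFPN} or \code{Trace} object.
#' @return \code{places}, \code{transitions} and \code{arcs} return the
#'   corresponding data frame; \code{parameters} the named numeric vector;
#'   \code{traceTimes} the sampled pt values; \code{traceSeries} the value
#'   matrix (or a single species' vector when \code{species} is given).
#' @name accessors
NULL

#' @rdname accessors
#' @export
places <- function(x) x@places

#' @rdname accessors
#' @export
transitions <- function(x) x@transitions

#' @rdname accessors
#' @export
arcs <- function(x) x@arcs

#' @rdname accessors
#' @export
parameters <- function(x) x@parameters

#' @rdname accessors
#' @export
traceTimes <- function(x) x@times

#' @rdname accessors
#' @param species optional place id naming one column of the series.
#' @export
traceSeries <- function(x, species = NULL) {
    if (is.null(species)) return(x@series)
    if (!species %in% colnames(x@series))
        stop("unknown species in trace: ", species)
    unname(x@series[, species])
}

#' @rdname accessors
#' @export
traceMeta <- function(x) x@meta
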