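# Interchange: JSON model documents (exact round-trip), CSV traces with
# deterministic formatting, DOT export, and a stable model fingerprint.

model_document <- function(net) {
    pl <- net@places; tr <- net@transitions; ar <- net@arcs
    list(
        format = "terpnet-hfpn",
        version = 1L,
        places = lapply(seq_len(nrow(pl)), function(i) list(
            id = pl$id[i], kind = pl$kind[i], initial = pl$initial[[i]],
            compartment = pl$compartment[i], label = pl$label[i])),
        transitions = lapply(seq_len(nrow(tr)), function(i) {
            out <- list(id = tr$id[i], kind = tr$kind[i],
                        compartment = tr$compartment[i])
            if (tr$kind[i] == "continuous") out$speed <- tr$speed[i]
            else {
                upd <- tr$update[[i]]
                out$update <- list(when = upd$when, set = as.list(upd$set))
            }
            out
        }),
        arcs = lapply(seq_len(nrow(ar)), function(i) list(
            kind = ar$kind[i], source = ar$source[i], target = ar$target[i],
            weight = ar$weight[i], threshold = ar$threshold[i])),
        parameters = as.list(net@parameters))
}

#' Write / read an HFPN model document
#'
#' Models are exchanged as UTF-8 JSON with top-level keys \code{places},
#' \code{transitions}, \code{arcs} and \code{parameters}; expressions are
#' stored as strings in the restricted grammar and numbers at full
#' precision, so \code{readModel(writeModel(net))} reproduces the network
#' exactly.
#'
#' @param net an \code{\linkS4class{HFPN}}.
#' @param path file path.
#' @param validate check the network on read (default TRUE); violations
#'   are surfaced as errors.
#' @return \code{readModel} returns the \code{HFPN};
#'   \code{writeModel} invisibly returns \code{path}.
#' @export
writeModel <- function(net, path) {
    json <- jsonlite::toJSON(model_document(net), auto_unbox = TRUE,
                             digits = NA, pretty = FALSE, null = "null")
    writeLines(json, path, useBytes = TRUE)
    invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path, validate = TRUE) {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e) stop("malformed model document '",
                        path, "': ", conditionMessage(e), call. = FALSE))
    for (key in c("places", "transitions", "arcs", "parameters"))
        if (is.null(doc[[key]]))
            stop("model document is missing required key '", key, "'",
                 call. = FALSE)
    pls <- lapply(doc$places, function(p) {
        for (key in c("id", "kind", "initial"))
            if (is.null(p[[key]]))
                stop("place entry missing key '", key, "'", call. = FALSE)
        list(id = p$id, kind = p$kind, initial = p$initial,
             compartment = p$compartment %||% "default",
             label = p$label %||% p$id)
    })
    trs <- lapply(doc$transitions, function(t) {
        if (is.null(t$id) || is.null(t$kind))
            stop("transition entry missing 'id' or 'kind'", call. = FALSE)
        upd <- NULL
        if (!is.null(t$update))
            upd <- list(when = t$update$when,
                        set = unlist(t$update$set))
        list(id = t$id, kind = t$kind,
             speed = t$speed %||% NA_character_,
             compartment = t$compartment %||% "default", update = upd)
    })
    ars <- lapply(doc$arcs, function(a) {
        for (key in c("kind", "source", "target"))
            if (is.null(a[[key]]))
                stop("arc entry missing key '", key, "'", call. = FALSE)
        list(kind = a$kind, source = a$source, target = a$target,
             weight = as.character(a$weight %||% 1),
             threshold = as.character(a$threshold %||% 0))
    })
    params <- unlist(doc$parameters)
    if (is.null(params)) params <- numeric()
    hfpn(pls, trs, ars, parameters = params, validate = validate)
}

#' Write / read a trace as CSV
#'
#' First column \code{time_pt}, then one column per place in network
#' declaration order, header row mandatory. Values are printed with 17
#' significant digits so doubles round-trip exactly and identical runs
#' produce byte-identical files.
#'
#' @param trace a \code{\linkS4class{Trace}} with at least one sample.
#' @param path file path.
#' @return \code{readTrace} returns a \code{Trace} (meta limited to what
#'   the CSV carries); \code{writeTrace} invisibly returns \code{path}.
#' @export
writeTrace <- function(trace, path) {
    if (length(trace@times) == 0L) stop("trace is empty")
    fmt <- function(v) sprintf("%.17g", v)
    header <- paste(c("time_pt", colnames(trace@series)), collapse = ",")
    rows <- vapply(seq_along(trace@times), function(i)
        paste(c(fmt(trace@times[i]), fmt(trace@series[i, ])), collapse = ","),
        "")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(header, rows), con, useBytes = TRUE)
    invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1L] != "time_pt")
        stop("trace file must start with a 'time_pt' column")
    times <- as.numeric(df[[1L]])
    series <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(series) <- "double"
    se <- if (length(times) > 1L) times[2L] - times[1L] else NA_real_
    new("Trace", times = times, series = series,
        meta = list(dt = NA_real_, sample_every = se, source = path))
}

#' Export a network as DOT (Graphviz)
#'
#' Places are ellipses, transitions boxes; inhibitory arcs end in a tee
#' arrowhead and test arcs are dashed. Every compartment holding at least
#' one continuous place becomes a cluster subgraph; regulatory (generic)
#' nodes sit outside the clusters.
#'
#' @param net a valid \code{\linkS4class{HFPN}}.
#' @return DOT source as a single character string.
#' @export
exportDot <- function(net) {
    pl <- net@places; tr <- net@transitions; ar <- net@arcs
    q <- function(x) paste0('"', x, '"')
    node_lines <- function(ids, kinds) {
        shapes <- ifelse(kinds == "place", "ellipse", "box")
        sprintf("    %s [shape=%s];", q(ids), shapes)
    }
    cluster_cmps <- unique(pl$compartment[pl$kind == "continuous"])
    lines <- c("digraph hfpn {", "  rankdir=LR;")
    ci <- 0L
    for (cmp in cluster_cmps) {
        ci <- ci + 1L
        lines <- c(lines,
            sprintf("  subgraph cluster_%d {", ci),
            sprintf('    label="%s";', cmp),
            node_lines(pl$id[pl$compartment == cmp], "place"),
            node_lines(tr$id[tr$compartment == cmp], "transition"),
            "  }")
    }
    outside_p <- pl$id[!pl$compartment %in% cluster_cmps]
    outside_t <- tr$id[!tr$compartment %in% cluster_cmps]
    lines <- c(lines,
        if (length(outside_p)) sub("^    ", "  ", node_lines(outside_p, "place")),
        if (length(outside_t)) sub("^    ", "  ", node_lines(outside_t, "transition")))
    style <- ifelse(ar$kind == "inhibitory", " [arrowhead=tee]",
             ifelse(ar$kind == "test", " [style=dashed]", ""))
    lines <- c(lines,
        sprintf("  %s -> %s%s;", q(ar$source), q(ar$target), style),
        "}")
    paste(lines, collapse = "\n")
}

#' Stable fingerprint of a network
#'
#' Polynomial rolling hash over the canonical serialised model document;
#' identical networks always hash identically, and any structural or
#' parameter change alters the digest with high probability. Used for run
#' provenance, not cryptography.
#'
#' @param net an \code{\linkS4class{HFPN}}.
#' @return 8-hex-digit character string.
#' @export
modelFingerprint <- function(net) {
    json <- jsonlite::toJSON(model_document(net), auto_unbox = TRUE,
                             digits = NA, pretty = FALSE)
    bytes <- utf8ToInt(json)
    h <- 5381
    # Horner with a sub-2^31 modulus keeps everything exact below 2^53
    for (i in seq_along(bytes))
        h <- (h * 33 + bytes[i]) %% 2147483647
    sprintf("%08x", as.integer(h))
}
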