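# Trace analysis: operational definitions of the qualitative behaviours the
# scenarios are expected to show (oscillation, monotone accumulation,
# growth-rate deceleration, fold changes). All pure functions of the trace.

#' Count prominent peaks in a species' time series
#'
#' A peak is a strict local maximum whose height exceeds both neighbouring
#' minima (the series minima between it and the adjacent peaks, or the
#' series ends) by at least \code{prominence}. Counting is invariant under
#' uniform vertical shifts, and under common scaling of the series and the
#' prominence.
#'
#' @param trace a \code{\linkS4class{Trace}}.
#' @param species place id present in the trace.
#' @param prominence minimum height above both flanking minima (> 0),
#'   in concentration units. Default 1.
#' @return integer peak count.
#' @examples
#' t <- seq(0, 4 * pi, by = 0.01)
#' tr <- new("Trace", times = t,
#'           series = matrix(sin(t), ncol = 1, dimnames = list(NULL, "x")),
#'           meta = list())
#' countPeaks(tr, "x", 0.5)  # 2
#' @export
countPeaks <- function(trace, species, prominence = 1) {
    stopifnot(prominence > 0)
    x <- traceSeries(trace, species)
    n <- length(x)
    if (n < 3L) return(0L)
    peak <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
    if (!length(peak)) return(0L)
    bounds <- c(1L, peak, n)
    count <- 0L
    for (j in seq_along(peak)) {
        left_min <- min(x[bounds[j]:peak[j]])
        right_min <- min(x[peak[j]:bounds[j + 2L]])
        if (x[peak[j]] - left_min >= prominence &&
            x[peak[j]] - right_min >= prominence)
            count <- count + 1L
    }
    count
}

#' Monotone non-decrease of a species
#'
#' TRUE iff every successive difference of the sampled series is at least
#' \code{-tol}.
#'
#' @inheritParams countPeaks
#' @param tol nonnegative slack on each successive difference.
#' @return logical.
#' @export
isMonotoneNondecreasing <- function(trace, species, tol = 1e-9) {
    x <- traceSeries(trace, species)
    length(x) < 2L || all(diff(x) >= -tol)
}

#' Time at which a species' growth decelerates
#'
#' Growth rates are centred finite differences on the sampled points; the
#' windowed rate at a sample is the mean rate over the trailing
#' \code{window} pt. The deceleration time is the earliest sampled time at
#' which the windowed rate falls below \code{drop_fraction} times the
#' maximum windowed rate observed before it; \code{NA} if that never
#' happens (e.g. for any exactly linear series).
#'
#' @inheritParams countPeaks
#' @param window trailing window width in pt; must span at least 3 samples.
#' @param drop_fraction fraction in (0, 1) of the running-maximum rate.
#' @return sampled time (pt) or \code{NA_real_}.
#' @export
decelerationTime <- function(trace, species, window = 10, drop_fraction = 0.5) {
    stopifnot(drop_fraction > 0, drop_fraction < 1)
    x <- traceSeries(trace, species)
    t <- traceTimes(trace)
    n <- length(x)
    if (n < 3L) return(NA_real_)
    if (window < 2 * stats::median(diff(t)))
        stop("window must span at least 3 samples")
    idx <- 2:(n - 1)
    rate <- (x[idx + 1L] - x[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
    rt <- t[idx]
    w <- vapply(seq_along(rt), function(i)
        mean(rate[rt > rt[i] - window & rt <= rt[i]]), 0)
    run_max <- -Inf
    for (i in seq_along(w)) {
        if (is.finite(run_max) && run_max > 0 &&
            w[i] < drop_fraction * run_max)
            return(rt[i])
        run_max <- max(run_max, w[i])
    }
    NA_real_
}

#' Terminal fold change between two traces
#'
#' Ratio of the final sampled value of \code{species} in trace \code{a} to
#' that in trace \code{b}.
#'
#' @param a,b \code{\linkS4class{Trace}} objects containing \code{species}.
#' @param species place id.
#' @return numeric ratio; errors when the terminal value of \code{b} is 0.
#' @export
terminalFoldChange <- function(a, b, species) {
    va <- traceSeries(a, species); vb <- traceSeries(b, species)
    tb <- vb[length(vb)]
    if (tb == 0)
        stop("terminal value of '", species, "' in the reference trace is 0")
    va[length(va)] / tb
}

#' Summarise a species' qualitative behaviour
#'
#' @inheritParams countPeaks
#' @param tol monotonicity slack (see
#'   \code{\link{isMonotoneNondecreasing}}).
#' @param window,drop_fraction deceleration parameters (see
#'   \code{\link{decelerationTime}}).
#' @return list: \code{species}, \code{n_peaks}, \code{monotone},
#'   \code{deceleration_time} (pt or \code{NA}), \code{terminal_value}.
#' @export
behaviorReport <- function(trace, species, prominence = 1, tol = 1e-9,
                           window = 10, drop_fraction = 0.5) {
    x <- traceSeries(trace, species)
    list(species = species,
         n_peaks = countPeaks(trace, species, prominence),
         monotone = isMonotoneNondecreasing(trace, species, tol),
         deceleration_time = decelerationTime(trace, species, window,
                                              drop_fraction),
         terminal_value = x[length(x)])
}
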