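# The five canonical simulation conditions: switch settings, parameter
# overrides and the timed crosstalk script.

.DISABLED_THRESHOLD <- 1e9  # "inhibition deactivated" = unreachable threshold

scenario_settings <- function(id) {
    off <- .DISABLED_THRESHOLD
    switch(as.character(id),
        "1" = list(  # normal sesquiterpene production, MEV only
            switches = c(MEV_switch = TRUE, MEP_switch = FALSE,
                         crossSwitch = FALSE),
            params = c(theta_mevp_atp = off, theta_atp_pmk = off,
                       theta_fpp_mk = off, theta_fos_dxr = off,
                       cross_script = 0)),
        "2" = list(  # normal monoterpene production, MEP only
            switches = c(MEV_switch = FALSE, MEP_switch = TRUE,
                         crossSwitch = FALSE),
            params = c(theta_mevp_atp = off, theta_atp_pmk = off,
                       theta_fpp_mk = off, theta_fos_dxr = off,
                       cross_script = 0)),
        "3" = list(  # ATP overproduction: mutually antagonistic feedback
            switches = c(MEV_switch = TRUE, MEP_switch = FALSE,
                         crossSwitch = FALSE),
            params = c(k_atp = 30, theta_mevp_atp = 80,
                       theta_fpp_mk = off, theta_fos_dxr = off,
                       cross_script = 0)),
        "4" = list(  # FPP overproduction: FPP -> MK feedback loop
            switches = c(MEV_switch = TRUE, MEP_switch = FALSE,
                         crossSwitch = FALSE),
            params = c(theta_mevp_atp = off, theta_atp_pmk = off,
                       theta_fpp_mk = 10, theta_fos_dxr = off,
                       cross_script = 0)),
        "5" = list(  # fosmidomycin-triggered MEP -> MEV crosstalk
            switches = c(MEV_switch = FALSE, MEP_switch = TRUE,
                         crossSwitch = FALSE),
            params = c(theta_mevp_atp = off, theta_atp_pmk = off,
                       theta_fpp_mk = off,
                       cross_script = 1)),
        stop("unknown scenario id: ", id, " (must be 1..5)"))
}

#' Configure one of the five simulation scenarios
#'
#' Applies a scenario's switch states and parameter overrides to the full
#' terpenoid model: (1) MEV pathway alone, no inhibition; (2) MEP pathway
#' alone, no inhibition; (3) ATP production raised to 30 unit/pt with the
#' MEVP -> ATP-production threshold at 80 units and the ATP -> PMK
#' inhibitory arc active; (4) the FPP -> MK threshold lowered from 100 to
#' 10 units; (5) MEP active with the crossSwitch script arming fosmidomycin
#' injection at t >= 150 pt, the fosmidomycin -> DXR arc and the crosstalk
#' arcs live. "Inhibition deactivated" is realised as a threshold of 1e9
#' (the divergence bound), so the network structure is identical across
#' scenarios. Pure: identical arguments yield identical configurations.
#'
#' @param id scenario 1..5.
#' @param params complete parameter vector (default
#'   \code{\link{defaultParameters}(1)}); scenario settings are applied on
#'   top of it, then \code{overrides}.
#' @param overrides named numeric vector/list of user parameter overrides
#'   (applied last; may override scenario settings, e.g.
#'   \code{cross_script = 0} to disable the crosstalk in a control run).
#' @param t_end,dt horizon and step, stored in the configuration.
#' @return list with elements \code{net} (the configured
#'   \code{\linkS4class{HFPN}}) and \code{config} (id, switch states,
#'   applied parameters, t_end, dt).
#' @examples
#' cfg <- configureScenario(3)
#' parameters(cfg$net)[["k_atp"]]  # 30
#' @export
configureScenario <- function(id, params = defaultParameters(1L),
                              overrides = list(), t_end = 300, dt = 0.1) {
    sc <- scenario_settings(id)
    p <- unlist(params)
    p[names(sc$params)] <- sc$params
    ov <- unlist(overrides)
    if (length(ov)) {
        if (is.null(names(ov)) || any(names(ov) == ""))
            stop("overrides must be named")
        unknown <- setdiff(names(ov), names(p))
        if (length(unknown))
            stop("unknown parameter override(s): ",
                 paste(unknown, collapse = ", "))
        p[names(ov)] <- ov
    }
    net <- buildModel(p)
    # switch states are initial values of the generic switch places
    pl <- net@places
    for (s in names(sc$switches))
        pl$initial[[match(s, pl$id)]] <- unname(sc$switches[[s]])
    net@places <- pl
    list(net = net,
         config = list(id = id, switch_states = as.list(sc$switches),
                       parameters = p, overrides = as.list(ov),
                       t_end = t_end, dt = dt,
                       seed = attr(params, "seed")))
}

#' Run a simulation scenario
#'
#' Configures scenario \code{id} (see \code{\link{configureScenario}}) and
#' simulates it over [0, t_end]. Deterministic given its arguments.
#'
#' @inheritParams configureScenario
#' @param sample_every sampling interval in pt.
#' @return a \code{\linkS4class{Trace}} whose meta block records the full
#'   run configuration.
#' @examples
#' \donttest{
#' tr <- runScenario(1, defaultParameters(1), t_end = 50)
#' isMonotoneNondecreasing(tr, "sesquiterpene", 1e-9)
#' }
#' @export
runScenario <- function(id, params = defaultParameters(1L), t_end = 300,
                        dt = 0.1, sample_every = 1, overrides = list()) {
    cfg <- configureScenario(id, params, overrides, t_end = t_end, dt = dt)
    runSimulation(cfg$net, t_end = t_end, dt = dt,
                  sample_every = sample_every,
                  meta = list(scenario = id, config = cfg$config,
                              seed = attr(params, "seed")))
}
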