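# The MEV + MEP terpenoid biosynthesis model: canonical inventory, the 19
# enzymatic reactions, and assembly of the full 66-place / 101-continuous-
# transition HFPN network.

# -- canonical inventory -----------------------------------------------------
# 61 continuous places: 42 metabolites (19 MEV-side, 23 MEP-side including
# the inhibitor fosmidomycin) plus 19 enzymes. MEP-side species duplicated
# from the cytosolic pathway carry the "_2" suffix.

.MEV_METABOLITES <- c(
    "acetyl_CoA", "acetoacetyl_CoA", "CoA", "H2O", "HMG_CoA", "NADPH",
    "NADP", "mevalonate", "ATP", "ADP", "MEVP", "MEVPP", "PO3", "CO2",
    "IPP", "DMAPP", "GPP", "FPP", "sesquiterpene")
.MEV_ENZYMES <- c("AACT", "HMGS", "HMGR", "MK", "PMK", "MVD", "IDI",
                  "GPPS", "FPPS", "STPS")
.MEP_METABOLITES <- c(
    "G3P", "pyruvate", "DXP", "CO2_2", "NADPH_2", "NADP_2", "MEP", "CTP",
    "PPi", "CDP_ME", "ATP_2", "ADP_2", "pCDP_ME", "CMP", "MEcycPP",
    "protein_diol", "protein_disulfide", "HMBPP", "IPP_2", "DMAPP_2",
    "GPP_2", "monoterpene", "fosmidomycin")
.MEP_ENZYMES <- c("DXS", "DXR", "MCT", "CMK", "MDS", "HDS", "HDR",
                  "GPPS_2", "MTPS")
.SWITCHES <- c("MEV_switch", "MEP_switch", "crossSwitch")
.MODULATORS <- c("atp_rate_mod", "fpp_mk_threshold_mod")

# pathway inputs replenished by nonzero zeroth-order production
.SOURCE_METABOLITES <- c("acetyl_CoA", "ATP", "NADPH", "H2O",
                         "G3P", "pyruvate", "CTP", "ATP_2", "NADPH_2",
                         "protein_diol")

#' The 19 enzymatic reactions of the MEV and MEP pathways
#'
#' Stoichiometry of the ten mevalonate-pathway reactions (cytosol, labels
#' "1".."10") and the nine methylerythritol-phosphate-pathway reactions
#' (plastid, labels "A".."I"), in order of occurrence. Protons are omitted
#' throughout and water is omitted as an MEP-side product; the IPP/DMAPP
#' isomerase (reaction 7) is modelled forward-only.
#'
#' @return list of reaction definitions, each a list with elements
#'   \code{order}, \code{substrates} (named weights), \code{products}
#'   (named weights), \code{enzyme} and \code{compartment}.
#' @examples
#' length(reactionTable())  # 19
#' reactionTable()[[3]]$substrates  # HMG-CoA:1, NADPH:2
#' @export
reactionTable <- function() {
    rx <- function(order, substrates, products, enzyme, compartment)
        list(order = order, substrates = substrates, products = products,
             enzyme = enzyme, compartment = compartment)
    mev <- list(
        rx("1", c(acetyl_CoA = 2),
               c(acetoacetyl_CoA = 1, CoA = 1), "AACT", "cytosol"),
        rx("2", c(acetoacetyl_CoA = 1, acetyl_CoA = 1, H2O = 1),
               c(HMG_CoA = 1, CoA = 1), "HMGS", "cytosol"),
        rx("3", c(HMG_CoA = 1, NADPH = 2),
               c(mevalonate = 1, CoA = 1, NADP = 2), "HMGR", "cytosol"),
        rx("4", c(mevalonate = 1, ATP = 1),
               c(MEVP = 1, ADP = 1), "MK", "cytosol"),
        rx("5", c(MEVP = 1, ATP = 1),
               c(MEVPP = 1, ADP = 1), "PMK", "cytosol"),
        rx("6", c(MEVPP = 1, ATP = 1),
               c(IPP = 1, PO3 = 1, CO2 = 1, ADP = 1), "MVD", "cytosol"),
        rx("7", c(IPP = 1), c(DMAPP = 1), "IDI", "cytosol"),
        rx("8", c(IPP = 1, DMAPP = 1), c(GPP = 1), "GPPS", "cytosol"),
        rx("9", c(IPP = 1, GPP = 1), c(FPP = 1), "FPPS", "cytosol"),
        rx("10", c(FPP = 1), c(sesquiterpene = 1), "STPS", "cytosol"))
    mep <- list(
        rx("A", c(G3P = 1, pyruvate = 1),
               c(DXP = 1, CO2_2 = 1), "DXS", "plastid"),
        rx("B", c(DXP = 1, NADPH_2 = 1),
               c(MEP = 1, NADP_2 = 1), "DXR", "plastid"),
        rx("C", c(MEP = 1, CTP = 1),
               c(CDP_ME = 1, PPi = 1), "MCT", "plastid"),
        rx("D", c(CDP_ME = 1, ATP_2 = 1),
               c(pCDP_ME = 1, ADP_2 = 1), "CMK", "plastid"),
        rx("E", c(pCDP_ME = 1),
               c(CMP = 1, MEcycPP = 1), "MDS", "plastid"),
        rx("F", c(MEcycPP = 1, protein_diol = 1),
               c(HMBPP = 1, protein_disulfide = 1), "HDS", "plastid"),
        rx("G", c(HMBPP = 1, NADPH_2 = 1),
               c(IPP_2 = 1, DMAPP_2 = 1, NADP_2 = 1), "HDR", "plastid"),
        rx("H", c(IPP_2 = 1, DMAPP_2 = 1), c(GPP_2 = 1), "GPPS_2", "plastid"),
        rx("I", c(GPP_2 = 1), c(monoterpene = 1), "MTPS", "plastid"))
    c(mev, mep)
}

#' Entity census of the terpenoid model
#'
#' The canonical lists of continuous places (61: 42 metabolites + 19
#' enzymes), generic switch places (3), generic parameter modulators (2),
#' continuous transitions (101: 19 reactions + production and degradation
#' for each of the 41 non-inhibitor metabolites) and generic transitions.
#'
#' @return list with elements \code{continuous_places}, \code{switches},
#'   \code{modulators}, \code{continuous_transitions},
#'   \code{generic_transitions}.
#' @export
inventory <- function() {
    mets <- c(.MEV_METABOLITES, .MEP_METABOLITES)
    pd <- setdiff(mets, "fosmidomycin")
    rt <- reactionTable()
    list(
        continuous_places = c(.MEV_METABOLITES, .MEV_ENZYMES,
                              .MEP_METABOLITES, .MEP_ENZYMES),
        switches = .SWITCHES,
        modulators = .MODULATORS,
        continuous_transitions = c(
            vapply(rt, function(r) paste0("t_r", r$order), ""),
            paste0("t_prod_", pd), paste0("t_deg_", pd)),
        generic_transitions = c("t_script_crossSwitch", "t_inject_fosmidomycin"))
}

required_parameter_names <- function() {
    mets <- setdiff(c(.MEV_METABOLITES, .MEP_METABOLITES), "fosmidomycin")
    c(paste0("k_", c(1:10, LETTERS[1:9])),
      paste0("prod_", setdiff(mets, "ATP")),
      paste0("deg_", mets),
      "k_atp", "theta_mevp_atp", "theta_atp_pmk", "theta_fpp_mk",
      "theta_fos_dxr", "t_fos", "k_fos_rate", "cross_script")
}

#' Build the full terpenoid HFPN model
#'
#' Assembles the complete MEV + MEP network: 61 continuous places, 3 on/off
#' switches, 2 parameter modulators, the 19 reaction transitions (normal
#' arcs for substrates/products, a test arc from each enzyme), one
#' production and one degradation transition per non-inhibitor metabolite
#' (101 continuous transitions in total), the fosmidomycin injection script,
#' the four inhibitory arcs (MEVP -> ATP production, ATP -> PMK,
#' FPP -> MK with its threshold read from the modulator place,
#' fosmidomycin -> DXR), and the crosstalk arcs from IPP_2/DMAPP_2 into the
#' cytosolic GPP/FPP synthase steps, consumed only while crossSwitch holds.
#'
#' Switch gating is multiplicative inside the speed expressions: MEV_switch
#' gates reactions 1-7, (MEV_switch OR crossSwitch) gates reactions 8-10,
#' MEP_switch gates reactions A-I.
#'
#' @param params complete named parameter vector, e.g. from
#'   \code{\link{defaultParameters}}.
#' @return a validated \code{\linkS4class{HFPN}}.
#' @examples
#' net <- buildModel(defaultParameters(1))
#' sum(transitions(net)$kind == "continuous")  # 101
#' nrow(places(net))                           # 66
#' @export
buildModel <- function(params) {
    params <- unlist(params)
    missing <- setdiff(required_parameter_names(), names(params))
    if (length(missing))
        stop("incomplete parameter set; missing: ",
             paste(missing, collapse = ", "))

    compartment_of <- function(id)
        if (id %in% c(.MEV_METABOLITES, .MEV_ENZYMES)) "cytosol" else "plastid"

    pls <- c(
        # the system fills from its sources; only the terminal terpene pools
        # start nonzero so product fold changes are defined against controls
        lapply(c(.MEV_METABOLITES, .MEP_METABOLITES), function(id)
            continuousPlace(id,
                initial = if (id %in% c("sesquiterpene", "monoterpene")) 1 else 0,
                compartment = compartment_of(id))),
        lapply(c(.MEV_ENZYMES, .MEP_ENZYMES), function(id)
            continuousPlace(id, initial = 1,
                compartment = compartment_of(id))),
        list(
            genericPlace("MEV_switch", FALSE, "regulatory"),
            genericPlace("MEP_switch", FALSE, "regulatory"),
            genericPlace("crossSwitch", FALSE, "regulatory"),
            genericPlace("atp_rate_mod", unname(params[["k_atp"]]), "regulatory"),
            genericPlace("fpp_mk_threshold_mod", unname(params[["theta_fpp_mk"]]),
                         "regulatory")))

    mass_action <- function(k, enzyme, substrates) {
        terms <- unlist(mapply(function(s, w) rep(s, w),
                               names(substrates), substrates, SIMPLIFY = FALSE))
        paste(c(k, enzyme, terms), collapse = " * ")
    }

    trs <- list(); ars <- list()
    addt <- function(x) trs[[length(trs) + 1L]] <<- x
    adda <- function(x) ars[[length(ars) + 1L]] <<- x

    for (r in reactionTable()) {
        tid <- paste0("t_r", r$order)
        kname <- paste0("k_", r$order)
        base <- mass_action(kname, r$enzyme, r$substrates)
        speed <- switch(r$order,
            "8" = sprintf(
                "k_8 * GPPS * (ifelse(MEV_switch, IPP * DMAPP, 0) + ifelse(crossSwitch, IPP_2 * DMAPP_2, 0))"),
            "9" = sprintf(
                "k_9 * FPPS * GPP * (ifelse(MEV_switch, IPP, 0) + ifelse(crossSwitch, IPP_2, 0))"),
            "10" = sprintf("ifelse(MEV_switch | crossSwitch, %s, 0)", base),
            if (r$compartment == "cytosol")
                sprintf("ifelse(MEV_switch, %s, 0)", base)
            else sprintf("ifelse(MEP_switch, %s, 0)", base))
        addt(continuousTransition(tid, speed, r$compartment))
        for (s in names(r$substrates)) {
            w <- r$substrates[[s]]
            # reactions 8/9 can also fire on crosstalk flux; their cytosolic
            # precursors must only be drawn while the MEV gate is up
            if (r$order %in% c("8", "9") && s %in% c("IPP", "DMAPP"))
                w <- sprintf("ifelse(MEV_switch, %d, 0)", w)
            adda(arcSpec("normal", s, tid, weight = w))
        }
        for (p in names(r$products))
            adda(arcSpec("normal", tid, p, weight = r$products[[p]]))
        adda(arcSpec("test", r$enzyme, tid, threshold = 0.5))
    }
    # crosstalk arcs: MEP-side precursors feed the cytosolic prenyl synthases
    adda(arcSpec("normal", "IPP_2", "t_r8", weight = "ifelse(crossSwitch, 1, 0)"))
    adda(arcSpec("normal", "DMAPP_2", "t_r8", weight = "ifelse(crossSwitch, 1, 0)"))
    adda(arcSpec("normal", "IPP_2", "t_r9", weight = "ifelse(crossSwitch, 1, 0)"))

    for (id in setdiff(c(.MEV_METABOLITES, .MEP_METABOLITES), "fosmidomycin")) {
        cmp <- compartment_of(id)
        prod_speed <- if (id == "ATP") "atp_rate_mod" else paste0("prod_", id)
        addt(continuousTransition(paste0("t_prod_", id), prod_speed, cmp))
        adda(arcSpec("normal", paste0("t_prod_", id), id))
        addt(continuousTransition(paste0("t_deg_", id),
                                  sprintf("deg_%s * %s", id, id), cmp))
        adda(arcSpec("normal", id, paste0("t_deg_", id)))
    }

    # feedback and inhibitor arcs (thresholds may read a modulator place)
    adda(arcSpec("inhibitory", "MEVP", "t_prod_ATP", threshold = "theta_mevp_atp"))
    adda(arcSpec("inhibitory", "ATP", "t_r5", threshold = "theta_atp_pmk"))
    adda(arcSpec("inhibitory", "FPP", "t_r4", threshold = "fpp_mk_threshold_mod"))
    adda(arcSpec("inhibitory", "fosmidomycin", "t_rB", threshold = "theta_fos_dxr"))

    # timed script: crossSwitch flips at t_fos when the scenario arms it;
    # fosmidomycin then accumulates at k_fos_rate unit/pt
    addt(genericTransition("t_script_crossSwitch",
        when = "cross_script >= 1 & time >= t_fos",
        set = c(crossSwitch = "TRUE"), compartment = "regulatory"))
    addt(genericTransition("t_inject_fosmidomycin",
        when = "crossSwitch & time >= t_fos",
        set = c(fosmidomycin = "fosmidomycin + k_fos_rate * dt"),
        compartment = "regulatory"))

    hfpn(pls, trs, ars, parameters = params)
}
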