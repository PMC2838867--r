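Package: terpnet
Title: Hybrid Functional Petri Net Simulation of Terpenoid Biosynthesis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A hybrid functional Petri net (HFPNe) engine for metabolic pathway
    simulation, together with a complete dynamic model of the mevalonate (MEV)
    and methylerythritol-phosphate (MEP) terpenoid biosynthesis pathways.
    Continuous places hold metabolite concentrations, continuous transitions
    fire at rate-law speeds under threshold-gated enabling (test arcs for
    enzymes, inhibitory arcs for feedback loops), and generic places and
    transitions implement on/off switches, parameter modulators and timed
    scripts. Includes the five canonical simulation scenarios (normal
    sesquiterpene and monoterpene production, ATP and FPP feedback-loop
    overproduction, and fosmidomycin-triggered MEP-to-MEV crosstalk), trace
    analysis utilities for oscillation, monotonicity and deceleration
    detection, reproducible sampling of unpublished kinetic parameters, and
    JSON/CSV/DOT interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
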