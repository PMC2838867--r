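---
title: "Modelling terpenoid biosynthesis as a hybrid functional Petri net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling terpenoid biosynthesis as a hybrid functional Petri net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terpnet)
```

## The model

Plants and many microbes synthesise the universal C5 terpenoid precursors
IPP and DMAPP through two independent routes: the mevalonate (MEV) pathway
in the cytosol, feeding sesquiterpene (C15) synthesis through GPP and FPP,
and the methylerythritol-phosphate (MEP) pathway in the plastid, feeding
monoterpene (C10) synthesis. terpnet represents both pathways, and the
regulatory links within and between them, as a hybrid functional Petri net
with extension (HFPNe):

* **Continuous places** hold metabolite concentrations in dimensionless
  concentration units ("unit"). Time runs in dimensionless Petri net time
  ("pt"). The model has 61 continuous places: 42 metabolites (19 MEV-side,
  23 MEP-side including the DXR inhibitor fosmidomycin) and 19 enzymes.
* **Continuous transitions** are processes firing at a speed (unit/pt)
  given by an expression over markings and parameters. There are 101:
  19 enzymatic reactions (Tables of both pathways, protons omitted and
  MEP-side water omitted so the census closes) plus one production and one
  degradation transition for each of the 41 non-inhibitor metabolites.
* **Generic places** implement regulation: three boolean on/off switches
  (`MEV_switch`, `MEP_switch`, `crossSwitch`) and two numeric parameter
  modulators (`atp_rate_mod`, read by the ATP production speed, and
  `fpp_mk_threshold_mod`, read by the FPP → MK inhibitory arc threshold).
  66 places in all.
* **Arcs**: normal arcs move mass with stoichiometric weights; test arcs
  attach each enzyme to its reaction without consuming it (enzyme marks are
  therefore constant through every simulation); inhibitory arcs disable a
  transition while the inhibitor marking is at or above the arc threshold
  (strict inequality enables). Four inhibitory arcs encode the regulation:
  MEVP ⊣ ATP production (threshold 80 units when armed), ATP ⊣ PMK,
  FPP ⊣ MK (threshold 100 units by default, 10 in the overproduction
  scenario), and fosmidomycin ⊣ DXR.
* **Generic transitions** are guarded assignments: a timed script flips
  `crossSwitch` at 150 pt when a scenario arms it, after which fosmidomycin
  accumulates at 2 unit/pt.

Speed laws are irreversible mass action, `v = k · E · Π substrates` (the
enzyme factor is constant), with zeroth-order production for the ten
source metabolites and first-order degradation elsewhere. Switch gating is
multiplicative: reactions 1–7 carry a `MEV_switch` factor, reactions 8–10
fire when `MEV_switch` *or* `crossSwitch` is up, and reactions A–I carry
`MEP_switch`. The crosstalk is modelled by additional substrate arcs from
the plastidial pools `IPP_2`/`DMAPP_2` into the cytosolic GPP and FPP
synthase transitions; their weights are the guard `ifelse(crossSwitch, 1, 0)`
(and symmetrically the cytosolic substrate arcs of those two reactions are
guarded by `MEV_switch`), so each side of the pathway is only drawn on
while its gate is up. Expression-valued weights are the one extension
beyond plain numeric stoichiometry, and exist precisely for this guarded
consumption.

## Firing semantics and numerics

Simulation is an explicit fixed-step discretisation of the continuous
firing rule, default `dt = 0.1` pt, sampled every 1 pt:

1. all transition speeds are evaluated simultaneously on the pre-step
   marking, with threshold enabling applied;
2. each place changes by `dt · (inflow − outflow)`;
3. a **starvation guard** protects nonnegativity: for every place whose
   total demanded consumption this step exceeds its marking, each
   consuming transition is scaled by the smallest availability fraction
   `marking/demand` over the places it draws on — a single simultaneous
   pass, deterministic and order-independent. A nearly empty pool
   throttles its consumers to exactly the available supply; in the limit
   `dt → 0` the semantics coincide with the mass-action rate equations.
   (The alternative of zeroing an over-demanding transition outright
   deadlocks under mass action: a speed `k·S1·S2` demands more than `S1`
   whenever `k·S2·dt > 1`, and blocking the reaction lets `S2` keep
   growing, locking the block in permanently.)
4. generic updates whose guards hold are applied after the continuous
   update, at the new time, in declaration order.

Markings can never go negative; a configurable overflow bound (default
1e9 unit) aborts divergent runs naming the offending place. Enabling
thresholds use `marking ≥ threshold` for normal/test arcs and strict
`marking < threshold` for inhibitory arcs; whether the original modelling
tool used strict or non-strict comparison is not documented anywhere we
know of, so strictness is a declared convention here. Euler stepping is
first order: the packaged accuracy checks require the source/decay motif
to hit its analytic steady state `k/d` within 1% at `dt = 0.01` and random
five-place mass-action networks to track a high-accuracy `deSolve::lsoda`
reference integration within 0.5% at `dt = 1e-3`. Convergence statements
are made for the smooth regime; near inhibition thresholds the dynamics
are discontinuous and trajectory phase depends on `dt`, as for any hybrid
system.

All expressions live in a deliberately small grammar — literals, parameter
and place names, `+ − × ÷`, `min`/`max`, `ifelse`, comparisons, boolean
connectives, and the reserved symbols `time` and `dt` — parsed once,
statically checked against the declared identifiers, and compiled to
closures, which keeps a 900 pt full-model run in the low seconds.

## Scenarios

Five conditions are packaged (`configureScenario`, `runScenario`).
"Inhibition deactivated" is realised as a threshold of 1e9 so the network
structure — and the 101/66 census — is identical in every scenario:

1. **Normal sesquiterpene production**: MEV on, MEP off, no inhibition.
2. **Normal monoterpene production**: MEP on, MEV off, no inhibition.
3. **ATP overproduction**: ATP production raised from 10 to 30 unit/pt
   (the modulator carries the value), MEVP ⊣ ATP-production armed at
   80 units, ATP ⊣ PMK armed. High ATP halts MEVPP synthesis; MEVP then
   accumulates, suppresses ATP production, and the system relaxes into
   sustained antiphase oscillations of ATP and MEVPP.
4. **FPP overproduction**: the FPP ⊣ MK threshold lowered from 100 to 10
   units. FPP rises past the threshold, throttles its own upstream supply,
   drains, and recovers — oscillating, with sesquiterpene accumulating in
   alternating fast and slow phases.
5. **Crosstalk**: MEP on, MEV off; at 150 pt the script flips
   `crossSwitch`, fosmidomycin accumulates and shuts DXR down, monoterpene
   production decelerates, and the plastidial IPP_2/DMAPP_2 flux is
   diverted into cytosolic GPP/FPP synthesis, raising sesquiterpene above
   the crosstalk-disabled control despite the MEV switch being off.

Scenario horizons default to 300 pt. Oscillation analyses read scenarios
3 and 4 over 900 pt and scenario 5 over 600 pt — the feedback relaxation
period approaches 300 pt under the slowest sampled source rates, so
"at least two peaks" needs the longer window; these are the problem sizes
used throughout the tests and the acceptance script.

## What is synthetic, and how it was calibrated

The pathway description prints the structure, the scenario settings
(10 → 30 unit/pt, thresholds 80 and 100 → 10, activation at 150 pt) and
nothing else; every rate constant is unpublished. The `synthetic` module
therefore samples them reproducibly: each parameter is drawn uniformly
from a documented range through a counter-based stream keyed by
`(seed, draw index, name)` — no global RNG state, identical triples give
identical values, and printed values are pinned (`low == high`).

The default ranges are not neutral: they are calibrated so the *printed*
thresholds lie inside the dynamic range of the pools they police, which is
a property the original model must have had for its published behaviour to
occur. Concretely (`defaultParameterRanges`):

* Rate constants sample `[0.01, 1]`, except five pinned slow steps.
  The ATP-coupled steps MK (`k_4 = 5e-4`), PMK (`k_5 = 2e-3`) and MVD
  (`k_6 = 1e-3`) must be slow, otherwise ATP is consumed the moment it is
  produced and can never re-cross its inhibition threshold: the feedback
  loop then settles onto the switching boundary (a sliding mode with the
  MEVP pool pinned at 80) instead of oscillating. The sliding-mode escape
  condition is `k_4 · mev_pool < k_5 · 80`, which with the mevalonate
  turnover pinned at 0.025 pt⁻¹ holds across the whole sampled flux range.
  The IPP isomerase (`k_7 = 0.05`) gives the prenyl segment a buffer with
  flux-independent discharge time `1/k_7 = 20` pt, deep enough that the
  FPP feedback cycles swing visibly (≥ 1 unit) even at the lowest sampled
  source rates; and the committed sesquiterpene synthase (`k_10 = 2e-3`)
  keeps the FPP pool 2–10× above the 10-unit scenario threshold while
  still draining it between cycles.
* Degradation rates come in families: pathway intermediates
  `[0.001, 0.002]` pt⁻¹ (slow turnover lets MEVP climb to 80 when PMK
  halts), substrate reservoirs `[0.005, 0.02]` (little of their production
  leaks before entering the pathway), ATP/ATP_2 and inert by-products
  `[0.05, 0.1]` (the ATP pool must drain within tens of pt for the
  oscillation period to fit the horizon), and the terminal terpenes 0
  (end products accumulate, which is also what makes the monotonicity
  checks of scenarios 1–2 meaningful).
* Source production rates sample `[1, 20]` unit/pt; the unpublished
  thresholds sample θ(ATP→PMK) ∈ `[20, 80]` and θ(fos→DXR) ∈ `[5, 50]`.

Initial marks are 0 unit for metabolites (the system fills from its
sources), 1 for enzymes, and 1 for the two terminal terpenes — the nonzero
product floor keeps fold changes against gated-off controls well defined.

These choices were derived analytically from the relaxation-oscillator
conditions above and then verified on seed grids disjoint from any seed
used during development; they are conventions of this reimplementation,
not published values, and all of them are plain entries in the range
object that callers can override.

**What the generator does not emulate.** Uniform (not log-uniform)
sampling is a simplicity choice. The synthetic parameters reproduce the
*qualitative* regimes — monotone accumulation, two feedback oscillations,
deceleration and crosstalk rescue — not the published figure curves; no
curve digitisation was attempted, so amplitudes and periods carry no
quantitative meaning. Real kinetic constants (e.g. from BRENDA) are
deliberately out of scope, as are triterpene/diterpene branches, reverse
isomerisation (the IPP ⇌ DMAPP step is forward-only so the transition
census closes), gene regulation, and stochastic semantics. Passing tests
therefore show that the implementation honours the published structure,
configuration and qualitative dynamics — not that it predicts real
metabolite concentrations.

## Trace analysis conventions

The published findings are read off simulation graphs, so the analysis
module fixes operational definitions: a **peak** is a strict local maximum
exceeding both flanking minima by a prominence (default 1 unit);
**monotone non-decreasing** allows a tolerance on successive differences
(default 1e-9); the **deceleration time** is the earliest sample at which
the trailing-window (10 pt) mean of the centred-difference growth rate
falls below half the running maximum; **fold changes** divide terminal
values. All are pure functions of the sampled trace.

## Reproducibility and interchange

Identical `(network, t_end, dt)` produce bit-identical traces; trace CSVs
print 17 significant digits so files are byte-identical across reruns and
doubles round-trip exactly. Models serialise to a JSON document (places /
transitions / arcs / parameters, expressions as strings) with exact
round-trip, shipped as `inst/extdata/terpenoid_model_v1.json`; a stable
polynomial hash of the canonical document fingerprints model versions in
CLI logs. DOT export draws places as ellipses, transitions as boxes,
inhibitory arcs with tee arrowheads and one cluster per metabolic
compartment.

## Known limitations

* Explicit Euler with threshold switching means trajectory *phase* near
  switching events is step-size dependent; peak counts and qualitative
  behaviour are robust to halving `dt`, individual sample values near
  switches are not.
* The starvation guard makes near-empty pools chatter at the step scale
  with amplitude of order `inflow · dt`; the default 1-unit peak
  prominence filters this.
* The census interpretation (enzymes counted among the 61 metabolite-like
  continuous places; production/degradation pairs for 41 metabolites) is
  the only enumeration we found consistent with the printed totals, but
  the original model files were not available to confirm it.
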