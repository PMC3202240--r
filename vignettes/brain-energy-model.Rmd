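---
title: "Methods: the neuron–astrocyte energy-metabolism models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the neuron-astrocyte energy-metabolism models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what is modelled, which
choices were open and how they were decided, and what the shipped test-suite
does and does not establish.

## The two models

A neuron and an astrocyte share an extracellular space and a capillary.
Each cell has nucleus, cytosol and a single lumped mitochondrion; the eight
compartment volumes (litres) are fixed and identical across variants:
Nn 0.033, Nc 0.33, Nm 0.0855, An 0.019, Ac 0.19, Am 0.0475, e 0.2, b 0.095.

The **classical** variant gives both cells the full chain: GLUT-mediated
glucose uptake; lumped glycolysis through the intermediates G6P, GAP
(two per glucose) and BPG, consuming ATP at the HK and PFK steps and
producing it at the lumped BPG→pyruvate step; an LDH pair interconverting
pyruvate and lactate; MCT carriers exchanging lactate and pyruvate with the
extracellular space; pyruvate import into the mitochondrion; a lumped TCA
representation over AcCoA, α-KG, SucCoA, Suc, Mal, OxAc (the citrate-
synthase entry step is lumped with aconitase/IDH so the species set stays
within the declared intermediates, and the cycle's GTP is treated as ATP); a
malate–aspartate-style NADH shuttle moving cytosolic reducing equivalents
into the mitochondrion without moving the nucleotides themselves; a lumped
electron transport chain; a creatine-kinase buffer in each cytosol; and
passive O₂/CO₂ diffusion among blood, extracellular space, cytosols and
mitochondria.

The **ANLSH** variant removes the neuron's glycolytic block and glucose
carriers and the astrocyte's entire mitochondrial block, and adds two
shuttle-specific neuronal reactions: a high-capacity MCT lactate import
(reaction 93) and an LDH step converting that lactate to pyruvate (94).
Which reactions belong to which variant is read from an enumeration string
in `inst/extdata/reactions.yaml` — the builders filter a single reaction
table by that list, so variant membership is data, not code.

Several declared routes ship with zero capacity (glucose efflux carriers,
mitochondrial creatine kinase, the cytosol↔mitochondrion creatine exchange,
HIF nuclear export). The network declares the physiological route; the
default parameterisation leaves it silent. This keeps three structural
invariants exact under the defaults — blood glucose is non-increasing
whenever it is not clamped, mitochondrial ATP is non-decreasing (there are
deliberately **no ATP sinks**, so ATP accumulation is the readout), and the
Cr/P-Cr pool is compartment-local — while letting a user switch any of the
routes on by editing the parameter file.

## Rate laws

Six forms cover every reaction: passive diffusion `γ(C_x − σC_y)`
(bidirectional, signed); facilitated transport and Michaelis–Menten
`V·C/(K_m+C)`; mass action; uncompetitive inhibition; and a saturating
product-form law `J_max·ΠC/(K+ΠC)` for multi-substrate steps, whose
two-substrate case is the familiar bimolecular form with K in mM². The
denominator deliberately carries the concentration *product* rather than
separate per-substrate terms; the exported evaluator implements exactly
this form, and the assembler extends it to the three-substrate electron
transport chain (NADH or FADH₂, ADP, O₂). Putting ADP inside the product
matters: it makes ATP synthesis shut itself off smoothly as the
mitochondrial adenine pool converts to ATP, which is what terminates the
starvation scenario's plateau. Reversible steps (LDH, creatine kinase, the
NADH shuttle) are explicit forward/backward reaction pairs rather than net
rate expressions, so every reaction stays within the six forms.

## Oxygen sensing and gene regulation

Per cell, cytosolic HIF is synthesised at a constant rate (first-order mass
action on a clamped unit precursor — zeroth-order kinetics are always
expressed explicitly), hydroxylated at rate `k·PHase·O₂·HIF` into a
degraded intermediate, and translocated first-order into the nucleus, where
it decays. PHase is a clamped enzyme species. At fixed O₂ the sensor is
linear; `hif_steady_state()` is its exact solution and doubles as the test
oracle.

Transcription of each regulated gene is basal plus a saturating HIF term
(`basal + V·H/(K+H)`); nuclear mRNA is exported (volume-scaled) and
degraded, cytosolic mRNA is translated and degraded, and protein scales the
V_max of the regulated reactions linearly through
`effective_capacity() = V_base · protein / protein_ref`. The normoxic
steady-state protein level *defines* `protein_ref`, computed in closed form
at build time, so a normoxic run starts exactly at its reference capacities
— no double counting. All seven genes (GLUT, MCT, HK, PFK, GAPDH, PK, LDH)
share one parameter set and therefore identical kinetics, which the suite
regression-tests.

The expression constants were calibrated once so that at 0.35 mM O₂ the
steady protein level reaches 2–3× its 7 mM level within 250 simulated
minutes (the shipped values give ≈2.4×), reproducing the qualitative
hypoxic induction the regulation layer represents; they were not revisited
afterwards. The gene-expression cascade lives in the ODE assembler as its
own block rather than in the numbered reaction table, because its
transcription term is a two-term sum and thus not a single declared-form
reaction; the HIF sensor itself is numbered (reactions 70–91).

## Numerical choices

* **Integration**: LSODA (stiff-capable) with rtol 1e-8 and atol 1e-11 on a
  1-minute output grid. The absolute tolerance is one decade tighter than
  the relative scheme's natural companion because several species (GAP,
  BPG, mitochondrial NADH) transit through near-zero values; at 1e-10 a
  depleted TCA intermediate can undershoot zero by ~2e-9 mM, outside the
  declared −1e-9 tolerance band. Negative excursions are *reported*, never
  clipped — silent clipping would quietly break the conservation tests.
* **Conservation by construction**: a reaction's rate J (mM/min) is
  referenced to its host compartment of volume V_h; a species in
  compartment V_i changes by `±stoich·J·V_h/V_i`. Amount conservation per
  reaction column is asserted structurally, and carbon drift over a closed
  250-min classical run stays at ~1e-15 relative.
* **Plateau detection**: a series is settled at the earliest time after
  which it stays within 1% (default) of its trailing-window mean (25 min
  window); the plateau value is that mean, and a series that never settles
  is reported not-attained rather than erroring. Clamped series plateau at
  t = 0 by construction.
* **Problem sizes**: the scenario runs use 250-min horizons (500 min for
  the lactate-shuttle runs, whose neuronal ATP plateaus near 250–300 min
  under normoxia and later under hypoxia); the recovery study uses 50
  observation times and 100 noise realisations. These sizes make every
  reported quantity stable to well under the tolerances used to test it.

## Scenarios

Normoxia (blood glucose 4.56 mM initial, O₂ 7 mM), hypoxia (O₂ 0.35 mM) and
glucose starvation (glucose 1 mM). Blood O₂ is always clamped — the
condition is a property of the perfusing blood. Blood CO₂ is an absorbing
pool. Starvation is modelled as a *clamp* (a constant 1 mM supply), the
reading consistent with a steady low-glucose feed; the alternative reading
(1 mM as a mere initial value) stays available via
`make_scenario("starvation", glucose_clamped = FALSE)`. The unreported
combination classical × starvation is allowed but flagged as an
extrapolation in the result metadata.

## The synthetic-data module

The generators emulate the statistical role of the study's raw inputs, not
their instrumentation:

* `perturb_parameters()` applies independent mean-one lognormal factors of
  stated CV to a parameter table — a robustness probe.
* `generate_noisy_timecourse()` overlays multiplicative lognormal (default)
  or additive Gaussian noise on a deterministic simulation, keeping the
  truth. Multiplicative noise is the default because concentrations and
  band intensities are positive quantities.
* `generate_expression_panel()` produces reference-normalised
  hypoxia/normoxia transcript panels with per-gene effect sizes defaulting
  to 2–3× — order-of-magnitude placeholders matching the regulation
  calibration, since only the direction of induction is quantitatively
  constrained. The panel deliberately allows a glycolytic "housekeeping"
  gene to be itself induced.
* `generate_uptake_series()` + `recover_transport_parameters()` form a
  self-contained identification exercise for the facilitated-transport law:
  the closed-pool uptake ODE has the exact implicit solution
  `K_m ln(C₀/C) + (C₀ − C) = V t`, evaluated by root finding, and the
  estimator fits it by Levenberg–Marquardt **on the log scale** (the
  correct criterion under multiplicative noise; linear-scale residuals are
  available for additive noise). When C₀ is not supplied it is estimated as
  a third parameter — anchoring it to the noisy first observation would
  bias V and K_m. In the linear regime (K_m ≫ C) the estimates become
  perfectly correlated; the fit detects the likelihood ridge through the
  parameter correlation, flags the pair non-identifiable, and reports the
  decay rate V/K_m from a log-linear regression instead.

What passing these tests shows: the estimator and generators are correct
under their declared noise laws. What they do not show: anything about real
RT-PCR efficiency, densitometry, or biological replicate structure — the
panels are direction-of-effect emulations only.

## Known limitations

* The full kinetic parameter set of the original compartmental models was
  not available; the shipped table carries literature-style defaults
  (`literature_default`) and declared estimates (`estimated`), never
  `supplementary` values. Plateau *magnitudes* are therefore indicative —
  e.g. neuron mitochondrial ATP reaches ≈206 mM (classical, normoxia)
  versus ≈367 mM (ANLSH) — while the orderings and directions of effect
  (shuttle > classical for neuronal ATP; hypoxia raises extracellular
  lactate and delays the shuttle's plateau; hypoxic expression dominates
  normoxic) are the tested claims. Under strict amount conservation the
  across-scenario mean neuronal-ATP fold-change is ≈1.6–2, more
  conservative than the headline factor the shuttle literature quotes.
* No ATP consumption, ion channels, glutamatergic stimulation, glycogen or
  pentose-phosphate branches: ATP accumulation is a production-efficiency
  readout, not a physiological steady state.
* The starvation plateau is set by exhaustion of the closed mitochondrial
  adenine pool (ADP 500 mM initially) — a bookkeeping ceiling, intentional
  given the no-sink design, not a bioenergetic prediction.
* SBML export covers compartments, species and the numbered reactions with
  their kinetic laws; the gene-expression layer is exported as species only.
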