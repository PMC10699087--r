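# boolkit

Qualitative, parameter-free simulation of signal-transduction networks
written in reaction-contingency (rxncon-style) notation, with a curated
executable model of NLRP3 inflammasome activation.

The NLRP3 inflammasome integrates two signals: a priming/licensing
signal (Signal 1: PAMPs or cytokines driving NFκB-dependent
transcription of NLRP3 and pro-IL-1β plus licensing phosphorylations)
and a trigger (Signal 2: ionophores, lysosome-destabilising particles,
or electron-transport-chain inhibitors). Whether a given combination of
stimuli, inhibitors and mutations can activate the inflammasome —
ASC-speck formation, caspase-1 processing, IL-1β/IL-18 release,
gasdermin D pores and pyroptosis — is a systems-level question that a
mechanistic network model can answer without kinetic parameters.
boolkit is aimed at systems biologists and immunologists who want to
encode such mechanistic knowledge precisely, test whether it suffices
to explain observed activation patterns, and run in-silico knockout,
inhibitor and mutation experiments.

## What it does

* **Knowledge-base layer** — elemental states
  (`NLRP3_[(S5)]-{P}`, `NEK7_[clobe]--NLRP3_[HD2LRR]`), typed elemental
  reactions (`AKT_P+_NLRP3_[(S5)]`, with a data-driven type registry),
  and contingencies: required `!`, inhibitory `x`, no-effect `0`, with
  nested AND/OR/NOT gates, system `[inputs]` and `[outputs]`. Plain TSV
  in, plain TSV out; a validator reports dangling targets, gate cycles
  and unproducible states.
* **Compiler** — a bipartite Boolean model: one node and one update
  rule per reaction, state (pool semantics: a state node means "some
  molecules carry this state"), component, input and output.
* **Simulator** — synchronous updates, natural off-state discovery,
  point/cycle attractor detection, scenarios with clamped inputs and
  model-variant flags, activation-ordered trajectory export.
* **Regulatory-graph export** — the production/consumption/
  required/inhibitory causality graph as GraphML or DOT.
* **Synthetic networks + oracle** — a seeded random-network generator
  and an independent reference interpreter used to property-test the
  compiler and simulator against each other.
* **The NLRP3 model** — 67 reactions and 142 contingency rows covering
  priming, licensing, the ATPase cycle, the Signal 2 trigger chain,
  assembly, outputs, the non-canonical caspase-4/5 axis and turnover,
  plus a 22-scenario experiment catalogue.

## Worked example

```r
library(boolkit)

kb <- load_nlrp3_network()
kb
#> <rxn_kb: 67 reactions, 142 contingency rows (23 gates), 42 components, 24 inputs, 22 outputs>

# LPS priming plus the ionophore nigericin: full activation
res <- run_scenario(kb, scenario("LPS+nigericin", c("LPS", "Nigericin")))
classify_outcome(res)
#> <activation_call LPS+nigericin: FULL_ACTIVATION>
#>   speck=TRUE casp1_active=TRUE il1b_release=TRUE il18_release=TRUE pyroptosis=TRUE bacterial_killing=TRUE

# nigericin alone: the trigger chain fires but nothing is expressed
classify_outcome(run_scenario(kb, scenario("nigericin", "Nigericin")))
#> <activation_call nigericin: NO_ACTIVATION>
#>   speck=FALSE casp1_active=FALSE il1b_release=FALSE il18_release=FALSE pyroptosis=FALSE bacterial_killing=FALSE
```

`FULL_ACTIVATION` means the attractor has the ASC–NLRP3 speck bond ON,
truncated (active) caspase-1 ON and IL-1β release ON; the other
readouts report IL-18 release, gasdermin-D-dependent pyroptosis and
bacterial killing. The whole catalogue — MCC950/G5/okadaic-acid
inhibition, the D305G and T346M CAPS mutations, LRR-truncated
miniNLRP3, intracellular LPS and KCl rescue — runs with
`scenario_truth_table(kb)`; individual entries are in
`scenario_catalogue()`. A command-line wrapper lives in
`inst/scripts/boolkit` (`boolkit validate <kb-dir>`,
`boolkit scenarios`, `boolkit graph`, `boolkit synth`).

See the methods vignette (`vignettes/boolkit-methods.Rmd`) for the
update-rule semantics, the off-state construction, every modelling
choice in the NLRP3 network, and the generator/oracle design.

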