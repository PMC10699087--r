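---
title: "Methods: reaction-contingency knowledge bases and bipartite Boolean simulation"
author: "boolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reaction-contingency knowledge bases and bipartite Boolean simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolkit)
```

## The formalism

boolkit encodes signal-transduction knowledge in rxncon-style
reaction-contingency notation. The atom of the representation is the
**elemental state**: a fact about a single site, such as a residue's
modification (`NLRP3_[(S5)]-{P}`), a bond between two domains
(`NEK7_[clobe]--NLRP3_[HD2LRR]`), or a free domain (`NLRP3_[HD2LRR]--0`).
Elemental states deliberately say nothing about the rest of the molecule;
this matches how site-specific experiments are reported and avoids
enumerating combinatorial microstates.

**Elemental reactions** are typed, decontextualised events
(`AKT_P+_NLRP3_[(S5)]`). The type registry — data, not code — declares
each type's class and effect pattern, so custom types (the nucleotide
cycle `aBind`/`aHy`/`aEx`, lipid binding `i`) are ordinary registry rows.
From the type and the subjects' loci we derive the consumed and produced
state sets; synthesis (`trsc`/`trsl`) produces the target component and
all of its neutral states, degradation (`deg`) removes the component.

**Contingencies** attach context: a reaction or output requires (`!`) or
is inhibited by (`x`) a state, an input, or a (possibly nested) Boolean
gate; `0` rows record curated "no effect" findings and compile to
nothing. Bracketed names denote the system boundary: inputs are clampable
stimuli, and bracketed contingency *targets* define outputs.

## Compilation to a bipartite Boolean model

`build_update_rules()` produces one node per reaction, per elemental
state (neutral and non-neutral), per component, per input and per
output, with one update expression each:

* **Reaction** `R`: presence of every participating component AND every
  inlined `!` modifier AND the negation of every `x` modifier.
* **Non-neutral state** `S`: component presence AND (some producer of
  `S` fired OR (`S` held and no consumer fired)). Production dominates
  consumption: a kinase/phosphatase pair that are both active keep both
  pool states TRUE.
* **Neutral state**: the same scheme; its producers include reverse
  reactions and every synthesis of its component, so newly translated
  protein arrives unmodified and unbound.
* **Component**: constant TRUE when nothing synthesises it; otherwise
  synthesis OR (presence and no active degradation), so constitutive
  machinery can never be permanently depleted while synthesised
  components genuinely appear and disappear.
* **Degradation with `!` state requirements** additionally consumes the
  required states of its target (contingent, "partial" degradation).
* **Output**: the conjunction of its inlined contingency rows.
* **Input**: identity — it holds its value unless clamped.

State nodes have **pool (existential) semantics**: `NLRP3_[(S5)]-{P}`
TRUE means *some* NLRP3 molecules are Ser5-phosphorylated, so a state
and its neutral partner are routinely TRUE together. This abstraction is
what lets synthesis bypass negative licensing (see below), and it is the
reason several design choices look unusual from a single-molecule
perspective.

### Why source states do not gate the reaction node

An alternative compilation folds a reaction's source states (the
`-{0}` it consumes) into the reaction rule itself. Under pool semantics
that choice is wrong, and measurably so: it couples the reaction layer
and the state layer one synchronous step out of phase, and every
constitutive kinase/phosphatase pair then oscillates with period 2–4
from any start in which the modified state is FALSE — the futile cycle
never reaches the both-states-TRUE steady state that the pool
abstraction intends. With sources acting only through the state layer
(they still define production and consumption), the pair settles in two
steps from a neutral start, which is exactly the behaviour the
reference interpreter's hand-traced unit test pins down. Source states
therefore gate *states*, not *reactions*.

### The natural off state

All experiments start from the **natural off state**: the point
attractor reached with every input FALSE. The canonical artificial
start (`initial_assignment(model, "neutral")`) sets components present,
neutral states TRUE, and everything else FALSE; reactions assume their
rule's value at the first step. Two alternatives fail structurally and
are worth recording:

* starting with *reaction nodes TRUE* produces every producible state
  once, which permanently switches on irreversibly produced states
  (proteolytic truncations, bonds with no dissociation reaction);
* starting with *all states TRUE* ("all-on", still available as an
  option) cannot relax for the same reason — a truncated caspase has no
  consuming reaction, so it, and everything downstream of it, stays ON.

For networks containing only reversible chemistry the two starts agree;
for realistic networks with irreversible proteolysis they cannot, and
the neutral start is the one that corresponds to a resting cell. The
test suite asserts the neutral-start off state is a point attractor
with every output OFF, and records the all-on comparison.

## The NLRP3 network

`load_nlrp3_network()` ships a curated model of NLRP3 inflammasome
regulation as three plain TSV tables (67 reactions, 142 contingency
rows, 23 gates): NFκB-dependent transcriptional priming under Signal 1;
posttranslational licensing through Ser5, Ser198, Ser295, Ser806 and
Tyr861 phosphorylation and LRR-domain K63-(de)ubiquitylation; the
ATPase cycle with MCC950; the Signal 2 trigger chain; assembly (NACHT
oligomerisation, PYD and CARD filaments, caspase-1 autoprocessing);
outputs (IL-1β/IL-18 maturation and release, gasdermin D pores,
pyroptosis, bacterial killing); the non-canonical caspase-4/5 axis; and
proteasomal/autophagosomal turnover. Modelling choices a reader should
know about:

* **Signal 2 as an input/output chain.** Trigger biology (ion fluxes,
  lysosomal damage, ETC inhibition) cannot be written molecularly, so it
  is a chain of placeholder outputs converging on centrosomal PI(4)P or
  exposed cardiolipin. Representative inputs stand for whole trigger
  classes (`Nigericin`, `extATP`, `PoreToxin`; `Type2Trigger`;
  `Imiquimod`, `CL097`).
* **K⁺ suppression.** `[Kefflux] = AND([ionicflux], NOT [extK])`, and
  lysosomal permeabilisation by type II triggers is likewise rescued by
  external KCl: `[LMP] = AND([HighLysoK], NOT [extK])`. The latter is
  written against external K⁺ directly so that type II triggers act
  without requiring a prior type I event.
* **Placeholder catalysts.** Transcription/translation use `Pol`/`Ribo`;
  unknown phosphatases and turnover catalysts use `X`. A generic
  phosphatase on Ser295 keeps that site reversible. IL-18 is
  constitutive (only NLRP3 and pro-IL-1β are primed).
* **AKT Ser473** is assigned to mTORC2, and the chemical AKT activator
  input is named `SC79`.
* **MCC950** baseline blocks only ADP→ATP exchange; the
  `mcc950-blocks-abind` variant extends the block to ATP binding of
  empty NLRP3. Both are shipped because the bare exchange block is
  bypassed by ATP binding to newly synthesised NLRP3 — an informative
  negative result, not a bug.
* **T346M** stabilises the open conformation (`<NLRP3open>` disjunct);
  the `t346m-bypasses-centrosome` variant additionally lifts the
  centrosomal-localisation requirement on NEK7 binding, which is the
  model-consistent consequence of PI(4)P-independent opening.
* **miniNLRP3** (LRR truncation) is an input adding `x` rows to the
  eight LRR-targeting reactions, transcribed verbatim from the curated
  contingency table (UIDs 175–182).

### Outcome classification

`classify_outcome()` reads six attractor readouts: the ASC–NLRP3 PYD
bond (speck), truncated caspase-1, IL-1β and IL-18 release, pyroptosis
and bacterial killing. `FULL_ACTIVATION` requires speck AND active
caspase-1 AND IL-1β release. Pyroptosis without a speck is reported as
`PORE_ONLY` — the non-canonical caspase-4/5 → gasdermin D route, which
intracellular LPS alone produces; the classifier never coerces this to
"no activation" because the pore and its feedback are real model
events even though NLRP3 itself stays silent. Oscillating readouts
would surface as an `OSCILLATING` summary rather than being coerced;
no shipped scenario oscillates.

## Simulation

Updates are synchronous and deterministic; asynchronous schemes are out
of scope. `simulate_to_attractor()` hashes visited assignments and stops
at the first revisit; cycle length is the distance between visits.
`max_steps` defaults to 500 — the fixture settles in under 40 steps from
every catalogue scenario, and failure to converge is a loud, typed
error carrying the partial trajectory. Trajectory export sorts rows by
the step of first activation (never-TRUE rows last, ties by declaration
order), which reproduces the familiar activation-sequence heat-map
layout.

## The synthetic-network generator and the oracle

`random_network()` emits small knowledge bases biased toward the motifs
the fixture exercises — kinase/phosphatase pairs, bond
formation/dissociation, (de)ubiquitylation, truncation, input-gated
transcription with translation and turnover, strict contingencies with
nested gates — rather than uniform random graphs, because those motifs
are where the semantics can go wrong. Generation is a pure function of
the configuration (including its seed); every emitted network passes
validation with zero errors by construction.

`reference_interpret()` is an independent oracle: it evaluates the
update semantics node by node directly from the knowledge base, with no
compiled rule expressions, and the central property test asserts
bitwise agreement with the compiled model over 200 seeded networks,
50 synchronous steps, two initial states and random clamp sets. The
suite uses networks of roughly 15–25 nodes; that size already covers
every rule constructor while keeping the whole property suite in tens
of seconds. What the generator does *not* emulate: realistic degree
distributions, large strongly connected feedback structures, and
quantitative kinetics — agreement on synthetic networks validates the
compiler, not the biology.

## Limitations

The model is qualitative: it predicts whether the inflammasome can
activate, not how much or how fast, so dose-dependent phenomena (e.g.
CAPS mutations whose effect is a quantitative shift of the ATPase
cycle, licensing that changes probabilities rather than possibilities)
are outside its reach — D305G correctly fails to activate here for
exactly that reason. Caspase-8-dependent, NEK7-independent activation,
TXNIP and cathepsin B are not modelled; within this network NEK7 is
absolutely required. Trajectory step counts are artefacts of the
synchronous abstraction: only ordering and attractor content carry
meaning.
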