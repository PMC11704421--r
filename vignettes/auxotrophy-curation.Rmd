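---
title: "Auxotrophy-based testing and curation of metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auxotrophy-based testing and curation of metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxofba)
```

## The idea

An auxotroph is a mutant that cannot synthesize a compound it needs and
therefore grows only when that compound is supplied. Each curated
auxotrophy observation is a sharp, two-sided test of a genome-scale
metabolic model (GEM): deleting the gene must abolish in-silico growth,
*and* opening the compound's exchange reaction must restore it. A model can
fail either side, and the two failure modes point at different defects:

* **Type I** — the knockout still grows in silico. The network contains a
  compensatory route (a promiscuous reaction, a too-permissive OR in a
  gene rule) that the organism does not actually have, at least not at
  functional capacity.
* **Type II** — the knockout is correctly lethal, but supplementing the
  rescuing compound does not help. Typically the compound has no exchange
  reaction, a gene rule is too strict, or a synthesis/salvage reaction is
  missing.

This package implements the full loop: the two-step simulation, the error
taxonomy, a vocabulary of replayable curation edits that fix each defect
class, the published curation set for the consensus yeast model, and a
systematic gene-by-compound screen that predicts every single-compound
auxotroph a model supports — the raw material for designing
nutrient-dependent strains and synthetic consortia.

## The simulation and its assumptions

Growth is flux balance analysis (FBA): maximize the biomass reaction's flux
subject to steady-state mass balance $Sv = 0$ and flux bounds
$l \le v \le u$. The usual FBA caveats apply — no kinetics, no regulation,
no metabolite dilution; alternative optima mean individual fluxes are not
unique, so only the optimal objective value is treated as reproducible.

A knockout is applied through the gene-protein-reaction (GPR) rules:
a reaction is disabled (bounds fixed to zero) when its boolean rule, with
deleted genes false and all others true, evaluates false. OR means
isoenzymes, AND means complex subunits.

Viability uses a relative threshold: a prediction is **viable** iff its
growth rate reaches `fraction` (default 0.01, i.e. 1%) of the wild-type
optimum of the same model on its default medium. The reference is
recomputed per model rather than hard-coded, so the policy transfers to any
input model; for the consensus yeast model the recomputed reference
reproduces the conventional 1%-of-wild-type cut. Two boundary conventions
are deliberate and documented here: growth exactly at the threshold counts
viable (the $\ge$ convention, since only predictions *falling below* the
threshold are inviable), and an infeasible knockout LP counts as growth 0
(no solution certainly falls below any threshold).

The two-step rescue procedure (`simulate_rescue()`):

1. open any medium supplements (they stay open in **both** steps — the
   condition-dependent cases require the background nutrient throughout),
   delete the record's genes, solve. Viable ⇒ `TYPE_I`.
2. otherwise, for each conjunct of the rescue specification (a disjunction
   of compound sets: rescue succeeds if *all* compounds of at least one set
   are supplied), open all of that conjunct's exchanges simultaneously to
   the uptake bound (default −1000 mmol/gDW/h, the conventional
   "unconstrained" uptake) and re-solve. Any viable conjunct ⇒ `CORRECT`,
   none ⇒ `TYPE_II`.

Compound resolution is three-valued, and the distinction carries meaning.
A compound matching nothing in the model makes the record `unresolvable`
— it cannot be scored and is excluded from accuracy denominators (set
`exclude_unresolvable = FALSE` in `accuracy()` to keep such records in).
A compound that *exists* in the model but has no exchange reaction is not
unresolvable: supplementation simply cannot work, which is exactly the
type-II signature of the heme-like cases whose cure is adding the missing
exchange.

## Curation edits

Seven edit kinds cover the observed defect classes: `block_reaction`,
`block_reverse` (forbid only the reverse direction), `set_gpr`,
`add_reaction`, `add_exchange` (created closed for uptake; rescues open it
at run time), and two biomass-pseudoreaction operators. Edits are data:
serializable to YAML/JSON, applied in order with all-or-nothing semantics
(`apply_edits()` aborts and reports the offending edit, leaving the input
untouched), and each carries provenance — the gene-compound pair that
motivated it and the error type it fixes.

The mass-balanced rescaling (`rescale_pseudoreaction()`) incorporates a new
species into a pooled pseudoreaction while conserving the pool's total
reactant mass. Coefficients are converted to masses
($m_i = |c_i| \cdot M_i$); with initial total $M_0$ and new-species mass
$m_\text{new}$, all reactant masses scale by
$f = M_0 / (M_0 + m_\text{new})$ and convert back. The operator also
accepts the *final* coefficient instead of the raw one (then
$f = (M_0 - m_\text{new}) / M_0$): curation tables print the end state, and
the encoded chitin edit (−0.02361 into the carbohydrate pool) is kept
verbatim as a final coefficient rather than recomputed, because the source
does not print the monomer masses it used. Both modes conserve total
reactant mass to machine precision and scale all pre-existing reactants
uniformly, so their pairwise ratios are preserved. Cofactor-style
additions (`pseudo_append()`, e.g. glutathione at −10⁻⁶) append without
rescaling: at that magnitude the mass perturbation is far below the
uncertainty of any biomass composition measurement.

`yeast9_curation_set()` encodes the published yeast curation:
8 blocked reactions (one reverse-only), 12 GPR rewrites, two
thiamine-pathway synthesis reactions plus a heme a exchange, and the two
pseudoreaction adjustments. Where the source table's row grouping leaves
the attribution of the ergosterol pairs ambiguous, the edits carry an
`ambiguous = TRUE` provenance flag rather than a silent guess. The
companion `synthetic_yeast9_skeleton()` is a small synthetic model — not
the genome-scale model — containing exactly the curated reactions with
their published equations, so the whole set can be applied and audited
offline; its polymeric pool masses (anhydroglucose 162.14, trehalose
342.30, N-acetylglucosamine 203.19 g/mmol) are this package's stand-in
values from standard residue masses.

## The solver

The LP backend is a dense bounded-variable two-phase primal simplex with
Bland's anti-cycling rule, written for this package and hidden behind the
narrow interface `lp_solve(obj, S, lb, ub)` so other backends can be
swapped in. Tolerances: 1e-9 on reduced-cost pivoting and phase-1
feasibility; test comparisons use 1e-6 on objectives. All bounds must be
finite (constraint-based models use ±1000 as "unbounded"). Correctness is
established empirically in the test suite: on hundreds of random
equality-constrained LPs the optimum matches exhaustive vertex enumeration
to 1e-6 and feasibility calls match exactly. Dense linear algebra is
entirely adequate at the problem sizes this package targets (tens of
reactions); genome-scale inputs work but are slow, and a sparse
factorizing backend would be the natural extension.

## The toy-model generator and what tests do (and do not) show

`make_toy_gem()` builds deterministic networks with planted ground truth:
a substrate exchange (uptake 10 mmol/gDW/h), an energy side reaction
(2 ATP per substrate), and per precursor a linear gene-labelled pathway
into a unit-coefficient biomass drain. The closed-form optimum
(uptake / total substrate cost) pins the solver; per-precursor flags plant
isoenzyme/complex rules, a type-I bypass trap, a type-II missing-exchange
trap, a medium-conditional cofactor branch, and a conjunctive
two-compound rescue. Each trap declares the curation edits that repair it,
so the generator rehearses the full observe–classify–curate–re-test loop
at toy scale. Topology is fully determined by the flags; the seed only
drives the synthetic-dataset noise (deliberately mismatched records), which
keeps the oracles exact.

Two independent oracles close the loop: a truth-table oracle that evaluates
GPR strings through R's own parser, and a graph-reachability oracle that
decides rescue viability with no linear programming at all (a reaction
direction fires when its bound allows it and its inputs are producible).
The reachability semantics coincides with "positive biomass flux is
feasible" on the generator's acyclic unit-coefficient networks — that is a
property of the fixtures, not of metabolism; on real networks with forced
by-products or internal cycles it would diverge, which is why it is an
oracle for fixtures and not a production code path.

Passing these tests therefore shows that the machinery — GPR algebra, LP
optimum, knockout application, two-step classification, edit replay,
screen enumeration — is correct. It does not validate any biological claim
about a real model: toy fixtures do not mimic yeast's pathway topology,
growth magnitudes, or biomass composition. Reproducing published
genome-scale numbers additionally requires the external model file and
curated dataset (see the README), and those numbers are sensitive to the
model point release.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `fraction` | 0.01 | — | viability threshold as a fraction of wild-type growth |
| `uptake_bound` (rescue) | −1000 | mmol/gDW/h | "unconstrained" uptake when testing a supplement |
| `uptake_bound` (substrate usage) | −10 | mmol/gDW/h | finite nutrient bound when swapping C/N/P/S sources |
| solver pivot/feasibility tol | 1e-9 | — | simplex internals |
| objective comparison tol | 1e-6 | — | test-level equality of optima |

The substrate-usage default sources (glucose, ammonium, phosphate,
sulfate) are configurable per call; the −10 bound for candidate sources is
the conventional finite-medium setting and is deliberately looser than a
measured uptake rate — the simulation asks "can this source support growth
at all", not "at what rate".

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the whole verification loop stays exhaustive: 1000 random GPR rules with
all deletion subsets up to 8 genes, 200 random LPs of at most 8 reactions
against full vertex enumeration, 100 randomized rescaling specs, and
trap fixtures of 5 precursors (≈30 reactions). These sizes make the
oracles exact rather than sampled; nothing in the design caps the package
itself at these sizes.

## Known limitations

* Only the FBA optimum is stable; reported flux vectors (including the
  flux-difference report that aids block-reaction curation) are one optimal
  solution among many. The report is a lead generator for inspection, and
  the choice of which reaction to block remains curatorial.
* No FVA, pFBA, MOMA, enzyme-cofactor coupling, or dilution-aware FBA;
  defect classes that need growth-coupled dilution of intermediates (the
  siroheme/polyamine style of failure) are out of reach of plain FBA and
  therefore of this package.
* SBML support is the Level 3 + fbc subset (species, stoichiometry, bound
  parameters, gene associations, objective); other SBML packages are
  ignored. Bracketed display ids are sanitized to legal SBML ids on write;
  the native JSON dialect is the lossless round-trip format.
* The systematic screen is single-compound by design; conjunctive rescues
  are only evaluated through datasets.
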