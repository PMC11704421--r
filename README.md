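# auxofba

Auxotrophy-based simulation and curation of genome-scale metabolic models
(GEMs), in R.

An auxotrophy observation — "deleting gene *g* is lethal unless compound
*c* is supplied" — is a two-sided test of a metabolic model. `auxofba`
runs that test as a two-step flux-balance simulation, classifies the
failures, and fixes them with replayable curation edits:

1. **Knockout step.** Delete the gene(s) through the reaction's
   gene-protein-reaction (GPR) boolean rule and maximize biomass flux
   subject to `S v = 0`, `lb ≤ v ≤ ub`. If growth stays at or above 1% of
   the wild-type optimum, the model wrongly predicts viability
   (**type I** error).
2. **Rescue step.** Otherwise open the compound's exchange reaction to
   unconstrained uptake (−1000 mmol/gDW/h) and re-solve. If no rescue set
   restores viability, the model wrongly predicts the supplement useless
   (**type II** error); otherwise the record is **correct**.

Rescue specifications are disjunctions of compound sets
(`homoserine | methionine + threonine`), knockouts may span several genes,
and medium supplements stay open through both steps — the shapes real
curated datasets have.

On top of the classifier the package provides:

* curation operators — block a reaction (or only its reverse direction),
  rewrite a GPR, add reactions/exchanges, and adjust biomass
  pseudoreactions with mass-conserving coefficient rescaling
  (`f = M0 / (M0 + m_new)` on reactant masses);
* `yeast9_curation_set()`, the machine-readable encoding of the published
  auxotrophy-derived curation of the consensus yeast model (8 blocks,
  12 GPR rewrites, 2 synthesis reactions + 1 exchange, 2 pseudoreaction
  adjustments), plus a small synthetic skeleton model to apply and audit
  it offline;
* `systematic_screen()`, the exhaustive gene × compound auxotroph
  predictor (knock out every gene, open every exchange one at a time) —
  input for designing nutrient-dependent cell factories and synthetic
  consortia;
* deterministic toy-GEM generators with planted ground truth and
  independent oracles (truth tables, LP vertex enumeration, graph
  reachability), so the entire pipeline is verifiable without any
  downloads;
* model I/O: SBML Level 3 + fbc and a lossless native JSON dialect; a
  bundled bounded-variable simplex LP solver behind a swappable backend
  interface; a command-line dispatcher
  (`system.file("scripts", "auxofba.R", package = "auxofba")`) with
  `simulate`, `curate`, `screen`, `evaluate`, `compare`, `fixture`, and
  `report` subcommands.

## Worked example

```r
library(auxofba)

# three biomass precursors, two planted model defects:
#   precursor 1: gene-free bypass  -> knockout wrongly stays viable (type I)
#   precursor 2: missing exchange  -> rescue cannot be simulated (type II)
fx <- make_toy_gem(toy_gem_config(3, 2,
  features = list("1" = "bypass", "2" = "no_exchange")))
model <- fx$model
policy <- default_policy(model)   # viability = 1% of wild-type optimum

run <- run_dataset(model, fx$truth$records, policy)
run$results[, c("knockout_genes", "rescue_spec", "ko_growth", "classification")]
#>   knockout_genes rescue_spec ko_growth classification
#> 1           g1_1          P1  2.857143         TYPE_I
#> 2           g2_1          P2  0.000000        TYPE_II
#> 3           g3_1          P3  0.000000        CORRECT
accuracy(run)
#> [1] 0.3333333
```

Record 1 keeps growing after the knockout (2.86/h ≈ wild type) because the
bypass shoulders the load; record 2 is correctly lethal but cannot be
rescued because `P2` has no exchange reaction. Each trap declares its
repair; applying the edits flips both records:

```r
repaired <- apply_edits(model, do.call(c, unname(fx$truth$repairs)))$model
accuracy(run_dataset(repaired, fx$truth$records, default_policy(repaired)))
#> [1] 1

systematic_screen(repaired, default_policy(repaired))$pairs
#>   gene exchange compound growth
#> 1 g1_1    EX_P1    P1[e]      4
#> 2 g1_2    EX_P1    P1[e]      4
#> 3 g2_1    EX_P2    P2[e]      4
#> 4 g2_2    EX_P2    P2[e]      4
#> 5 g3_1    EX_P3    P3[e]      4
#> 6 g3_2    EX_P3    P3[e]      4
```

After repair every pathway gene is essential and rescued by its own
precursor: exactly the planted truth, and exactly what the no-LP
reachability oracle enumerates.

Applying the yeast curation set works the same way on any model containing
the targeted reactions:

```r
cur <- apply_edits(synthetic_yeast9_skeleton(), yeast9_curation_set())$model
cur$reactions[["r_4048"]]$stoich[["chitin[c]"]]      # -0.02361
cur$reactions[["r_4598"]]$stoich[["glutathione[c]"]] # -1e-06
find_exchange(cur, "heme a")                         # "r_temp1"
```

## Vignette

`vignettes/auxotrophy-curation.Rmd` documents the model and its
assumptions, the error taxonomy, the rescaling arithmetic, viability
boundary conventions, solver design, what the toy generator does and does
not emulate, and known limitations.
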