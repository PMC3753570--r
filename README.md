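# boolfam

Exhaustive learning and analysis of Boolean logic model families for
signaling networks.

## The problem

Signal transduction can be modeled with Boolean logic: a prior knowledge
network (PKN) of signed causal interactions is refined into concrete
AND/OR/NOT wiring by training against perturbation phospho-proteomics data
(ligand stimuli switched on, kinases clamped off by inhibitors, protein
activities measured at early times and normalized to [0, 1]). Stochastic
optimizers return *a* well-fitting model; but within experimental error
there are usually *many*, and questions such as "which interactions are
certainly functional?", "which are unidentifiable?", and "what experiment
would tell the remaining candidates apart?" are properties of the complete
family of compatible models. boolfam computes that family exactly and
analyzes it.

## Method

The PKN is compressed (unobservable/uncontrollable and pass-through nodes
removed) and expanded into the hypergraph of candidate gates: one AND gate
per sign-consistent regulator subset of each node, so a logic model is a
gate subset read in sum-of-products form and the model space is `2^E` for
`E` candidate gates. A model is simulated to its quasi steady state per
experimental condition (synchronous updates; stimuli clamped to 0/1,
inhibited nodes clamped to 0) and scored against the discretized
measurements `x_i^j` by

```
MSE = (1 / n_compared) * sum_{i,j} (p_i^j - x_i^j)^2 ,   size = sum_gates |inputs|
```

computed in exact integer arithmetic on the discretization grid. Training is
the lexicographic discrete problem *minimize MSE, then size*, solved by a
complete branch-and-bound (oracle-tested against brute force), and the
family at tolerance `eps` is **every** model with
`MSE <= (1 + eps) * MSE_opt` and size within bound. Families are then
characterized by gate frequencies (always / never / variable), mutually
inclusive and exclusive modules, Global Truth Tables (the full input-output
behavior over all `2^k` input assignments), core predictions shared by all
behaviors, behavior clustering, and minimal discriminating experiment sets
(exact set cover over behavior pairs).

## Worked example

```r
library(boolfam)

cfg <- synth_config(n_nodes = 10, n_stimuli = 3, n_inhibitables = 1,
                    n_readouts = 3, edge_prob = 0.35, noise_sd = 0.05, seed = 9)
net  <- generate_pkn(cfg)            # random PKN with roles
inst <- generate_truth_and_data(net, cfg)
inst$hypergraph
#> Expanded hypergraph: 7 nodes, 32 candidate gates (model space 4294967296)

fam <- enumerate_models(inst$hypergraph, inst$dataset,
                        enumeration_config(fit_tolerance = 0.10))
fam
#> Model family: 2 models (tolerance 10%, size <= 4)
#>   optimum: MSE = 0.0008125, size = 4
```

Two models explain the data equally well (both at the optimal MSE
0.0008125 with size 4 — `family_mse_spectrum(fam)` shows a single MSE with
count 2). The frequency report says why:

```r
subset(hyperedge_frequencies(fam), class != "never")
#>    id target sources count frequency    class
#> 2   1    v08    +v02     2       1.0   always
#> 16 15    v09    +v02     1       0.5 variable
#> 27 26    v09    +v08     1       0.5 variable
#> 29 28    v09    -v01     2       1.0   always
#> 30 29    v10    -v03     2       1.0   always
```

Three gates are present in every family member (functional given the data);
readout `v09` can be driven either directly by `v02` or via `v08` — a
mutually exclusive pair the data cannot separate
(`mutually_exclusive_pairs(fam)` reports it with frequencies 0.5 / 0.5).
Since `v08` simply relays `v02` here, both wirings produce the same
input-output behavior:

```r
gtts <- group_by_gtt(fam)
length(gtts)                  # 1: the 2 models are experimentally indistinguishable
core_predictions(gtts)$n_core # 16 of 16 conditions are core predictions
```

With more than one behavior, `minimal_discriminating_set(gtts)` returns a
provably minimal set of experiments separating every pair of behaviors, and
`best_single_experiments(gtts)` ranks the simplest single conditions by
discriminating power.

File-based pipelines (`run_learn()`, `run_analyze()`, `run_behaviors()`,
`run_design()`) read standard Cytoscape SIF networks and MIDAS CSV datasets
and write deterministic CSV/JSON/Newick reports; a thin command-line wrapper
lives at `inst/cli/boolfam.R`.

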