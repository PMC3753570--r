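---
title: "Learning complete families of Boolean logic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning complete families of Boolean logic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolfam)
```

## The problem

Perturbation phospho-proteomics experiments probe a signaling network by
switching ligand stimuli on, clamping kinases off with small-molecule
inhibitors, and measuring the phosphorylation of a handful of proteins
shortly after stimulation. Given a prior knowledge network (PKN) of signed
causal interactions, one wants the Boolean logic models — concrete AND/OR/NOT
wirings compatible with the PKN — that best explain those measurements.

Stochastic training (genetic algorithms and the like) returns *some*
well-fitting models. But experimental error means many models fit the data
equally well within noise, and the scientific questions — which interactions
are certainly functional, which are unidentifiable, what experiment would
discriminate the remaining candidates — are questions about the *complete*
family of compatible models, not about any single member. boolfam therefore
makes completeness the contract: its optimizer and enumerator are exact, and
every downstream statistic is computed over the full family.

## Model space

The PKN is a signed digraph with three designated roles: stimuli,
inhibitables and readouts. Two structural passes precede learning:

* **Compression** removes undesignated nodes that cannot influence any
  readout or cannot be influenced by any input, and collapses pass-through
  undesignated nodes (indegree 1 or outdegree 1), multiplying edge signs
  along the collapsed path. Collapses that would create a self-loop are
  skipped so feedback semantics are preserved; designated nodes are never
  touched. This is the variant with a cartesian product restricted to
  single-input or single-output nodes, which avoids edge blow-up; published
  tool chains differ in the fine print of this rule set, and reproducing a
  specific historical gate count can require matching a specific variant.
* **Expansion** turns the compressed PKN into the hypergraph of candidate
  gates: for every node, one AND gate per non-empty, sign-consistent subset
  of its signed regulators, capped at `max_gate_size` inputs (default 4, the
  cap is reported in run metadata because published case studies do not
  state theirs). A gate containing a literal and its negation is always
  false and is dropped. A *logic model* is any subset of these gates, read
  per target as OR over its selected AND gates (sum-of-products). With
  `E` gates the model space is exactly `2^E`, which
  `search_space_size()` reports in arbitrary precision.

Canonical gate identifiers are assigned by sorting on (target, signed source
tokens) under C-locale (radix) string order, so ids are reproducible across
machines and input file orderings.

## Simulation and scoring

Predictions are quasi-steady states: stimuli are clamped to their condition
value (absent stimulus = 0), inhibited nodes are clamped to 0 overriding
their rule, all other nodes start at 0 and update synchronously until a
fixpoint, up to `3 * n_nodes` steps. Synchronous updating from a fixed
initial state makes the result deterministic and order-independent; on
acyclic hypergraphs it converges within `n_nodes` steps to the unique
fixpoint. With feedback loops the trajectory may oscillate; nodes still
changing during a probe window after `max_steps` are reported as *unresolved*
(`NA`) — a value, not an error, so scoring and enumeration stay total. An
unresolved prediction is penalized with the worst-case squared residual 1.
This penalty is this package's own convention (the treatment of unstable
nodes under feedback is genuinely open) and is the conservative choice: it
never makes an oscillating model look better than a stable one.

Measurements are normalized to `[0, 1]` (linear min–max per readout, or a
validating passthrough) and discretized to the grid `10^-precision`
(default 2 digits; the tie rule is half away from zero, stated explicitly
for reproducibility). Scoring then happens in exact integer arithmetic: the
sum of squared residuals is accumulated on the scaled grid (`10^(2p)` per
unit), so equal fits are exactly equal and tolerance thresholds are exact
comparisons, not floating-point coincidences. MSE is this scaled sum divided
by `n_compared * 10^(2p)`; missing measurements are excluded from
`n_compared` rather than imputed. The parsimony objective is model *size*:
the total number of gate inputs across selected gates.

## Optimization and enumeration

The training objective is lexicographic: minimize MSE first, then size. The
reference backend is a complete branch-and-bound, not a heuristic:

* Targets are processed in a topological order of the gate dependency graph,
  scheduling readout targets as early as their inputs allow; each target's
  gate subset determines its prediction vector across conditions
  incrementally, so residuals accrue as soon as a readout is decided.
* The admissible bound adds, for every undecided readout, the minimum
  achievable residual per entry (the better of predicting 0 or 1, or the
  clamped value); size is monotone and bounds the search directly. A
  subtree is pruned when this bound cannot beat the incumbent
  lexicographically (optimization) or exceeds the stated bounds
  (enumeration).
* In optimization mode, only the cheapest gate subset per distinct
  prediction vector of a target can participate in a lexicographic optimum,
  so per-target choices are built by a dynamic program over gates keeping
  the minimum-size mask per value vector. In enumeration mode every subset
  is a distinct model and is enumerated by size-bounded recursion instead.
* On cyclic hypergraphs the incremental scheme does not apply; the search
  falls back to exhaustive gate-by-gate recursion with fixpoint simulation
  at the leaves, still complete, with size and constant lower-bound pruning.

Tolerances follow the convention of treating fit error multiplicatively and
parsimony absolutely: the family at tolerance `eps` holds every model with
`MSE <= (1 + eps) * MSE_opt` (exact rational comparison with a `1e-9` guard
so boundary ties are always included) and `size <= size_bound`, where
`size_bound = "optimal"` resolves to the optimum's size. Families are
reported in lexicographic bit-vector order and two runs produce
byte-identical files. A safety cap (default `10^6` models) turns runaway
enumerations into an instructive error, since family size grows
exponentially with the tolerance.

The completeness contract is tested, not assumed: on batteries of synthetic
instances with up to 18 gates (including cyclic ones), the enumerator is
compared for set equality against brute force over all `2^E` subsets, at
tolerances 0, 2% and 10%; the simulator and scorer are separately validated
against an independent pure-R implementation on smaller instances.

## Behaviors (Global Truth Tables)

A model's Global Truth Table (GTT) is its prediction for every readout under
every one of the `2^k` assignments of the `k` inputs (all stimuli and all
inhibitables toggled independently, including inhibitors of unmeasured
nodes). Models sharing a GTT are experimentally indistinguishable, so the
family is grouped by GTT; groups are ordered by minimum member MSE, then
member count. Unresolved predictions participate in GTT equality as a third
symbol: two models that differ only in where they fail to converge are
still different behaviors in principle. *Core predictions* are the
conditions where all behaviors agree — predictions robust to model
uncertainty. Behaviors are clustered hierarchically under Hamming distance
on concatenated prediction vectors with average linkage (the linkage is a
package choice; nothing deeper hangs on it), and the dendrogram is exported
as Newick text. The input count is capped (default 20, i.e. about a million
conditions) to keep the table in memory; the cap errors loudly rather than
truncating.

## Family structure and experiment design

Presence frequencies across the family partition gates into *always*
(certainly functional given the data and tolerance), *never*, and
*variable* (unidentifiable). *Mutually inclusive* groups are maximal gate
sets with identical presence columns; *mutually exclusive* pairs are group
pairs of which exactly one side appears in every member — the interchangeable
modules whose free combination inflates family counts. Pairs are reported
only when both sides actually occur (frequencies in `(0,1)` summing to 1),
and `swap_effect()` quantifies each pair by rescoring every member with one
side swapped for the other: the MSE delta and the fraction of experimental
conditions whose readout predictions change.

Discriminating-experiment design is a set cover: a condition separates a
pair of GTTs when the tables differ there in at least one readout with both
predictions resolved (pair-level separation — one differing readout counts
the same as two, with per-readout counts reported alongside; unresolved
never separates, conservatively). `minimal_discriminating_set()` offers a
greedy cover and an exact branch-and-bound seeded by it (dominance-pruned;
the exact search is attempted when at most 5000 candidate conditions
remain, otherwise greedy plus a disjoint-pair lower bound are returned and
flagged). `best_single_experiments()` ranks single conditions by separated
pairs, then fewest active stimuli, then fewest active inhibitors — the
simplest maximally informative next experiment. One caveat worth knowing:
for three behaviors, pairwise differences can never be fully private (if B
and C differ at a condition, A differs from one of them there too), so
three-behavior instances always admit covers of size at most two; genuinely
larger minima require four or more behaviors.

## The synthetic generator

`generate_pkn()` and `generate_truth_and_data()` produce the instances the
test suite and the acceptance script run on: a random signed DAG (optionally
with feedback) over topologically ordered nodes, sources as stimuli, late
nodes as readouts, sampled inhibitables; a ground-truth gate subset biased
toward small gates (geometric bias, and every target feeding a readout
keeps at least one gate so parsimony stays informative); observations are
the truth's Boolean steady states plus additive Gaussian noise truncated to
`[0, 1]`, over the full factorial of input conditions or a sampled subset.
Everything is reproducible from one integer seed.

What this emulates: the instance *shape* of perturbation studies — roles,
factorial designs, bounded noisy measurements, missing values (via
unresolved truths) — and it yields a clean parameter-recovery surface: with
zero noise and the full factorial measured, the enumerated optimal family
provably contains a model with the truth's GTT, and under 5% noise with 10%
tolerance the truth's behavior is recovered in the large majority of seeded
instances (tracked at a 70% threshold in the suite).

What it deliberately does not emulate: *systematic* misfit. Real data are
graded and the true biology is not a Boolean model from the candidate
space, so real optimal MSEs are large and the 10% band above them is wide
enough to admit thousands of structurally distinct near-optima. Synthetic
truths live inside the candidate space and noise is unbiased, so synthetic
optima fit almost perfectly, the tolerance band above them is narrow, and
enumerated families are typically small — often a single model. Passing
tests on synthetic data therefore certify the machinery (completeness,
exactness, recovery), not the claim that synthetic instances exhibit
real-data-sized families; the package reports whatever multiplicity an
instance actually has.

## Numerical and design choices

* Discretization default of 2 digits: the published case studies' exact
  grids are not recoverable, so the precision is an explicit configuration
  knob, surfaced in run metadata and the CLI.
* Exact scaled-integer SSE rather than floating MSE: enumeration needs
  exact ties; all comparisons against tolerance bounds use an absolute
  `1e-9` guard only to protect the float multiplication `(1+eps)*SSE_opt`,
  never to widen the band by a representable amount.
* Fit tolerance applies to the exact rational MSE, not a rounded decimal.
* Determinism everywhere: fixed initial state, synchronous updates,
  radix-ordered canonical ids, lexicographic family order, deterministic
  tie-breaks in covers and rankings; two runs give byte-identical outputs.
* The test suite's problem sizes — batteries of 7–13-node networks with up
  to 18–34 candidate gates, 1000 fixpoint spot checks, 50-instance
  completeness batteries — were chosen so the whole suite exercises every
  guarantee at brute-force-checkable scale in well under a minute of
  search time.
* An external-solver backend slot exists behind the same interface
  (`backend = "external"`); it is intentionally unconfigured here and
  errors informatively. The native branch-and-bound is the reference
  implementation and the one all tests certify.

## Known limitations

* Exhaustive enumeration is exponential in the worst case; the
  branch-and-bound handles the desk-scale and mid-size instances this
  package targets, but case studies with hundreds of gates and wide
  tolerance bands are the territory of dedicated solver backends.
* Only steady-state semantics: no time-series fitting, no asynchronous or
  probabilistic updates, no multi-valued logic.
* Inhibitor semantics are clamp-to-0; graded inhibition (partial
  knock-down) is out of scope, as are Hill-type normalization transforms
  and multi-cell-line MIDAS files (the CellLine column is ignored).
* The unresolved-penalty rule for oscillating nodes is a convention; flags
  in outputs make its activation visible, but other conventions are
  defensible.
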