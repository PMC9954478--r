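---
title: "Methods: phonological network resilience and spreading activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phonological network resilience and spreading activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonet)
```

This vignette is the package's account of its methods: the models, the
parameters that matter, the numerical conventions, and what the synthetic
generators do and do not stand in for.

## 1. The phonological network

Nodes are words; an undirected edge joins two words exactly when their
phoneme sequences are at Levenshtein distance 1 — one addition, deletion,
or substitution of a single phoneme. Three conventions deserve note:

* **Homophones** (identical transcriptions) are kept as distinct nodes
  with *no* edge between them: the rule demands exactly one edit, and
  distance-0 pairs have zero. Merging them would silently change node
  counts and every percentage downstream.
* **Hermits stay in the graph.** Degree-0 words are first-class nodes.
  Around half of a realistic phonological lexicon is isolated, and the
  retrieval simulations depend on them (their landmark activation value
  identifies them in trajectory plots), so every serialization format the
  package writes preserves isolates — the edge-list format gains a
  `.nodes` manifest file for exactly this reason.
* **Construction is deterministic** and independent of entry order.
  Internally, candidate neighbor pairs are found by grouping words on
  wildcard keys (substitutions) and single-deletion images
  (additions/deletions), which is equivalent to the quadratic scan —
  the test suite proves the equivalence against a full
  dynamic-programming Levenshtein oracle — but scales to a
  19k-word lexicon.

Tokenization supports one-symbol-per-phoneme strings and
delimiter-separated symbols, because phonemic encodings in distributed
lexicons come in both flavours; an optional declared inventory turns
unknown symbols into named errors rather than silent nodes.

## 2. The damage protocol

Damage is cumulative random *edge* removal: stage *k* samples uniformly
from the edges that survived stage *k* − 1. This longitudinal design —
rather than independent draws from the intact network at each level —
is what lets one word be followed across damage levels, and it makes
edge sets strictly nested while the node set never changes (words are
not unlearned; they become harder to reach).

**Rounding.** Per-stage removal counts are the stage's *increment* of
the intact edge count, rounded **up** to a whole edge. For the canonical
schedule on a 31,267-edge network this gives removals of 3,127 then
6,254 per stage, i.e. remaining edge counts 28,140 / 21,886 / 15,632 /
9,378 / 3,124 — the per-stage ceiling is the unique simple rule
consistent with that published ladder, which no rounding of cumulative
targets reproduces. A small epsilon guards the ceiling against binary
floating-point noise (`0.1 × 10` is slightly above 1 in IEEE doubles).

**Seeding.** A damage schedule owns one RNG seed; the same
`(network, schedule)` pair reproduces the trajectory bit-exactly. All
seeded internals save and restore the caller's RNG state, so package
calls never perturb a user's random stream. By symmetry of uniform
sampling, every edge survives the 50%-removal stage with probability
0.5 — the suite checks this exchangeability over 200 seeded runs.

## 3. The metric panel

Per stage: edge count; giant component (GC) size and share; isolates
and share; islands (components of size ≥ 2 other than the GC) and their
word total; Louvain communities and modularity *Q* in the GC; mean
degree over the whole network and over the GC; mean local clustering in
the GC; ASPL in the GC. Conventions, chosen where the definitions are
genuinely open:

* **Edgeless graph GC** is a single node, the lexicographically
  smallest, so shares stay well-defined and ties are deterministic.
  (Shares only partition exactly when the GC has ≥ 2 nodes; on an
  edgeless graph the "GC" node is simultaneously an isolate.)
* **Clustering of degree < 2 nodes counts as 0**, not excluded; with
  heavy damage most GC nodes are degree-1 and exclusion would bias the
  mean upward exactly where the decline matters.
* **ASPL is computed exactly** (full BFS over the GC), not sampled:
  giant components at these problem sizes (≤ ~6.5k nodes) are
  tractable, and the resilience flag needs a stable point value.
* **Community detection** is Louvain greedy modularity maximisation at
  resolution 1 with a fixed seed. The heuristic is stochastic, so
  community *counts* are treated as descriptive; *Q* of the returned
  partition is checked in the tests against exhaustive search over all
  partitions on small two-clique graphs.
* **Resilience flag**: ASPL ≥ 1.5 × intact ASPL. Stage metrics are
  point values with no sampling distribution, so no inferential test is
  attached; the 1.5× heuristic (inclusive at the boundary) is the
  package's significance criterion, e.g. an intact ASPL of 6.05 sets
  the threshold at 9.075.

## 4. Spreading activation

One synchronous step maps the activation vector `a` to

$$a_i' = (1-d)\Big[r\,a_i + \sum_{j \in N(i)} \frac{(1-r)\,a_j}{\deg(j)}\Big],$$

followed by zeroing any value below the suppress threshold `s`.
Defaults: initial activation `a0 = 20` on the target alone, retention
`r = 0.5`, decay `d = 0`, `s = 0`, `t = 5` steps (activation is near
asymptote by five steps). Parameter meanings: `r` is the share a node
keeps after diffusing to neighbors; `d` is the share lost network-wide
per step (a transmission-deficit knob); `s` forces near-zero nodes to
exactly zero.

Three deliberate conventions:

* **Degree-0 semantics.** A hermit's outgoing `(1 − r)` share has
  nowhere to go and is *lost*, which is what produces the hermit
  landmark `a0 · r^t = 0.625`. Totals are therefore conserved only on
  graphs whose active nodes all have degree ≥ 1.
* **Order of operations**: retention+spread, then decay, then suppress,
  all synchronously from the time-*t* state. With uniform `d` and
  `s = 0`, placing decay before or after the spread is mathematically
  identical (the operators commute up to the same scalar), so the
  choice is observable only with `s > 0`, which the default analyses
  never use.
* **Per-word runs by default.** Retrieval is scored per target word —
  one run per (word, stage) — because the score is the target's
  *absolute* activation and co-activated targets would contaminate each
  other. A `joint = TRUE` co-activation mode exists behind a flag; by
  linearity its state is exactly the superposition of the separate
  runs, which the tests verify.

Linearity is the load-bearing property: the state under decay `d`
equals `(1 − d)^t` times the `d = 0` state, for every graph and initial
condition. That single identity entails the structural-protection
result — final-activation vectors across any two decay settings
correlate at exactly +1.0 — and the suite asserts both the identity (to
1e−12 against a dense transition-matrix-power oracle) and its
correlational consequence. The implementation uses a sparse
column-normalised operator (`Matrix`), accumulates in double precision,
and test comparisons use absolute tolerances of 1e−12 (algebraic
identities) or 1e−9 (iterated dynamics).

**Trajectory classification.** Following one word's final activation
across damage stages, five mutually exclusive patterns are assigned in
order: `always_isolate` (at the hermit sentinel everywhere),
`became_isolate` (sentinel at the end but not the start),
`became_size2_island` (two-node-island sentinel at the end but not the
start), `activation_increased` (final above first — the paradoxical
benefit of pruning a dense neighborhood), else `other_decreasing`.
Sentinels are *derived from the parameters* (`a0·r^t·(1−d)^t` and
`(a0/2)·(1−d)^t`), not hard-coded, so classification stays valid off
the defaults; sentinel comparisons use a 1e−9 absolute tolerance.

A note on the neighborhood-density effect: in a bare star the hub
settles at exactly `a0/2` regardless of leaf count, because degree-1
leaves return everything they receive. The density penalty the
retrieval literature describes comes from the *neighbors'* onward
connectivity draining activation away — final activation decreases
strictly in the neighbors' out-degree, which is the form the test suite
asserts.

## 5. The statistical layer

* **Activation–accuracy correlations** inner-join on word per group
  (aphasia type), require ≥ 3 common words, and report Pearson *r* with
  the standard two-sided *t*-based *p* on *n* − 2 df. No
  multiple-testing correction is applied, matching the descriptive use
  of the panel.
* **Error-location chi-square** is the textbook two-cell goodness of
  fit: observed counts of error *targets* in vs. outside the GC,
  expected proportions equal to the damaged network's node fractions,
  df = 1, no continuity correction. Severity groups map to damage
  stages (mild → 10% removed, very severe → 90% removed) in the study-2
  driver, pairing behavioural severity with structural damage.

## 6. Synthetic data: what it emulates, and what it does not

Real inputs — a 19k-word phonemic lexicon, picture-naming accuracies,
and error records from an aphasia database — are not redistributable,
so the generators emulate their *statistical structure*:

* **Lexicon.** Abstract symbols (inventory 16), word lengths 2–8 drawn
  from a mildly short-skewed distribution
  (0.12/0.18/0.20/0.18/0.12/0.10/0.10), transcriptions sampled uniquely.
  Short words over a small inventory form a dense core; long words are
  mostly isolates. The defaults were calibrated once so that a
  2000-word lexicon's network lands at a GC fraction of ~0.32–0.36 and
  an isolate fraction of ~0.60 — inside the target bands [0.20, 0.50]
  and [0.35, 0.70] that bracket the real network's 34% / 53% — and are
  not revisited per analysis. The generator does **not** reproduce
  English phonotactics, the real degree distribution's exact shape, the
  real network's size, or any actual stimulus item; passing tests
  demonstrate that the pipeline's logic is correct under a structurally
  faithful lexicon, not that any specific empirical value of the real
  lexicon would be reproduced.
* **Accuracy tables.** A planted expected Pearson correlation ρ:
  accuracy is `ρ·scale(activation) + noise·sqrt(1−ρ²)·N(0,1)`, mapped
  into [0.05, 0.95] by a monotone *linear* min–max transform. A linear
  map preserves correlation exactly, so the planted ρ is the expected
  recovered ρ, and `ρ = 1, noise = 0` yields *r* = 1 identically.
  (Planting on ranks instead would attenuate recovered Pearson *r* by
  the activation–rank correlation — activations are heavy-tailed — so
  rank-based planting was rejected.) Default ρ = 0.18, in the middle of
  the weak positive range reported for aphasic naming accuracy; the
  suite recovers it to ±0.03 over 500 replicates at n = 165.
* **Error records.** Targets sampled with weight `enrichment` (default
  1.7) for GC words, 1 otherwise. At 1,500 errors the chi-square
  rejects at α = 0.01 in ≥ 95% of seeded replicates — the power the
  analysis needs to be informative — while `enrichment = 1` stays at
  the null rate.

All generators are bit-reproducible from (spec, seed).

## 7. Problem sizes and determinism in the test suite

The suite runs entirely on generated data: oracle-equivalence checks
use ≤ 200-word lexicons (network construction vs. DP Levenshtein),
≤ 100-node graphs (ASPL/clustering vs. BFS/triangle counting),
≤ 20-node graphs (diffusion vs. matrix powers), and 6-node graphs
(modularity vs. exhaustive partition search). Structural monotonicity,
calibration, and resilience-flag behaviour run on 2000-word synthetic
lexicons — the size at which the giant component is large enough for
ASPL-based flags to stabilise — over fixed seed sets, keeping the whole
suite deterministic and under half a minute. The study drivers'
integration tests use 500-word lexicons.

## 8. Known limitations

* The package models a single-layer phonological network; semantic
  structure, multiplex phonology–semantics coupling, and interactive
  production architectures are out of scope.
* Damage is random edge removal only — no targeted attacks, no node
  removal, no weighted-edge redistribution.
* The phonological similarity rule is the discrete one-edit criterion;
  graded or feature-based similarity is not supported.
* Louvain community counts are heuristic-dependent; compare them only
  across runs with the same seed and resolution.
* Synthetic behavioural data validate recovery of *planted* effects;
  they cannot validate claims about any particular empirical dataset.
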