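# phonet

Resilience of the phonological network of the mental lexicon under
edge damage, with spreading-activation retrieval simulations.

## The problem

Words in the mental lexicon can be arranged as a network: each node is a
word, and an edge connects two words when the addition, deletion, or
substitution of exactly one phoneme turns one into the other (*kat* —
*at*, *kat* — *kats*). English phonological networks built this way have
a distinctive shape: roughly a third of words sit in one giant connected
component (GC), about half are *lexical hermits* (degree-0 isolates),
and the rest occupy small *lexical islands*. `phonet` is for researchers
in cognitive network science and the speech/language/hearing sciences
who want to ask three questions about such networks:

1. **Structure under damage.** How does the network degrade when
   connections — not words — are removed cumulatively at random
   (an analogue of retrieval deficits in aphasia, tip-of-the-tongue
   states, and other disorders where words are not *unlearned*, just
   harder to reach)?
2. **Processing on the damaged structure.** How does damage change
   lexical retrieval, simulated as spreading activation, and does the
   simulation track naming behaviour of people with aphasia?
3. **Structural protection.** Does the intact network's structure
   protect retrieval when the *process* (not the structure) becomes less
   efficient?

## The model

**Damage protocol.** Starting from the intact network with `E` edges,
stage *k* removes a uniformly random sample of the edges *surviving
stage k − 1*, so edge sets are nested and every word keeps its node at
every stage. The canonical schedule removes 10%, 30%, 50%, 70%, and 90%
of the intact edge count.

**Metric panel.** For each stage: edge count, GC size, isolates,
islands, Louvain communities and modularity *Q* in the GC, average
degree, average local clustering in the GC, and the average shortest
path length (ASPL) in the GC. Because stage values are points, not
distributions, resilience loss is flagged by the heuristic
ASPL ≥ 1.5 × intact ASPL.

**Spreading activation.** Retrieval of a target word places `a0` = 20
units on its node; each synchronous step, every node keeps proportion
*r* (retention, 0.5) of its activation and splits the rest equally among
its neighbors, the result decays by proportion *d*, and values below the
suppress threshold *s* are zeroed:

    a_i(t+1) = (1 − d) · [ r · a_i(t) + Σ_{j ∈ N(i)} (1 − r) · a_j(t) / deg(j) ]

After *t* = 5 steps the target's absolute activation is the retrieval
score. Two exact landmarks follow: a hermit ends at `20 · 0.5⁵ = 0.625`
and a word in a two-node island at `20 / 2 = 10`. Because the update is
linear, the state at decay *d* is exactly `(1 − d)^t` times the *d* = 0
state — so activation vectors at different decay settings correlate at
*r* = +1.0, which is the structural-protection result.

**Statistics.** Pearson correlations (with *t*-based *p*) between
simulated activation and per-word naming accuracy by group; per-word
activation-trajectory classification (always hermit, became hermit,
became a size-2 island, activation increased, otherwise decreasing) with
sentinels derived from the parameters; and a goodness-of-fit chi-square
comparing where naming errors fall (in vs. outside the GC) against the
damaged network's node fractions. Calibrated synthetic generators for
lexicons, accuracy tables (planted correlation), and error records
(planted GC enrichment) make the whole pipeline testable without any
external database.

## Worked example

```r
library(phonet)

lex  <- generate_lexicon(synth_lexicon_spec(n_words = 2000, seed = 42))
net  <- build_phon_network(lex)
traj <- apply_damage(net, damage_schedule(seed = 1))
panel <- summarize_trajectory(traj)
round(panel[, c("fraction_removed", "n_edges", "gc_size", "n_isolates",
                "avg_clustering_gc", "aspl_gc")], 3)
#>   fraction_removed n_edges gc_size n_isolates avg_clustering_gc aspl_gc
#> 1              0.0    3049     677       1206             0.278   4.042
#> 2              0.1    2744     651       1234             0.258   4.057
#> 3              0.3    2134     610       1286             0.202   4.185
#> 4              0.5    1524     554       1339             0.141   4.565
#> 5              0.7     914     461       1453             0.075   5.251
#> 6              0.9     304     181       1639             0.045   9.332
panel$resilience_lost
#> [1] FALSE FALSE FALSE FALSE FALSE  TRUE
```

Every structural column declines monotonically while isolates grow, yet
ASPL stays nearly flat until the last stage: the network is resilient
until ~90% of its connections are gone, when ASPL exceeds 1.5 × the
intact value and the resilience flag fires.

```r
hermits <- igraph::V(net)$name[igraph::degree(net) == 0]
simulate_word(net, hermits[1])$final
#> [1] 0.625                      # a lexical hermit's landmark value

words <- sample_targets(net, 50, seed = 2)
head(sweep_correlations(decay_sweep(net, words)), 3)
#>    d1  d2 r
#> 1 0.1 0.3 1
#> 2 0.1 0.5 1
#> 3 0.1 0.7 1
```

All ten decay-setting pairs correlate at exactly +1: words that are easy
to retrieve with efficient transmission stay easy when transmission
degrades.

The three study drivers `run_study1()`, `run_study2()`, and
`run_study3()` orchestrate these stages from one YAML configuration and
write CSV/GraphML outputs plus a reproducibility manifest; see
`?pipeline_config` and the methods vignette
(`vignettes/phonological-network-resilience.Rmd`).

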