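---
title: "Connectivity analysis of protease-inhibitor interaction webs"
author: "proteaseweb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity analysis of protease-inhibitor interaction webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteaseweb)
```

## The model

Proteolysis is regulated not only by direct cleavage of substrates but by
proteases cleaving other proteases (zymogen activation, catalytic-domain
removal) and their inhibitors (inactivating an inhibitor releases its
target protease). `proteaseweb` represents this *protease web* as a
directed graph: a cleavage is an edge from the protease to its substrate,
an inhibition an edge from the inhibitor to the inhibited protease. An
edge from A to B therefore means "A directly influences the activity or
abundance of B"; the sign of that influence (activation vs. inactivation)
is deliberately not modelled, because both directions of regulation
propagate influence equally through the graph.

Three modelling conventions matter and are fixed throughout:

* **Reachability includes the node itself.** Reachability of X is the
  number of nodes Y, X included, with a finite directed path X → Y.
  Self-inclusion is forced by the calibration that an isolated node has
  reachability 1 and every node of a strongly connected n-node network
  has reachability n; both are asserted in the tests.
* **Connectivity is arc-based.** A cleavage and an inhibition between the
  same ordered pair are stored as two edges (edge totals count both) but
  contribute a single arc to every path, reachability and betweenness
  computation. Self-loops (autolysis) are stored but never traversed,
  since reachability already counts the node itself.
* **The inverse cumulative curve is left-closed.** For each observed
  reachability value r the curve gives the fraction of nodes with
  reachability ≥ r. Its area over [0, n], normalized by the reference
  node count n, is the connectivity AUC; with this step convention the
  rectangle-sum integral is identically `mean(reachability) / n`, an
  identity the tests check to 1e-9 against an independent summation.

The *strongly connected core* is the largest strongly connected
component; its members all share one reachability value `r_core`. Tiers
are defined relative to the core alone: *upstream* nodes have
reachability strictly above `r_core` (they reach the core but cannot be
reached from it), everything else is *downstream*. We deliberately do not
hard-code any absolute boundary value: in real snapshots the gap between
tiers is an empirical feature of the data, not a parameter.

## Normalization choices

`reference_n` — the node count dividing the AUC — defaults to the
analysed network's own size. Across a perturbation series the original
network's count is frozen instead and removed nodes contribute zero
reachability, so AUC ratios compare like with like; the alternative
(renormalizing to the shrunken network) is available by computing a fresh
profile. For tissue-specific networks the default is each tissue's own
largest-component size, matching per-tissue inverse cumulative curves
expressed as percentages of that tissue's network; a common reference can
be passed for cross-tissue ratio work. Inverse cumulative curves can be
normalized against either the largest-connected-component size or the
full web size; the LCC is the default entry point in all examples
because connectivity questions are posed within the connected part.

## Perturbation suite

All perturbations only delete: edges below a confidence label, cleavages
of inhibitors that plausibly record trapping rather than inactivation
(cleavage P → I removed iff I carries inhibitor class S and P is a serine
or cysteine protease, or I is an A2M/PZP-style trap inhibitor — the rule
is class-based rather than a curated serpin list, with a flag for the
broader "any serine-protease inhibitor" reading), single nodes, connector
sets, or random edge subsets (`floor(f·|E|)` edges per draw, worst case =
minimum AUC across draws, which is unambiguous because deletion can only
lower AUC). Monotonicity — no perturbation ever increases any node's
reachability — is property-tested. Betweenness used by the connector
search is directed, endpoint-excluding, with equal splitting across tied
shortest paths; ties at the argmax are broken towards the
lexicographically smallest accession so the search is deterministic.

## Null models

Four matched ensembles contextualize an observed mean reachability:

* **ER** — uniform simple digraph with the observed node and arc counts.
* **BA** — sequential attachment forcing the observed out-degree
  multiset; nodes arrive in random order and emit arcs to prior nodes
  with probability proportional to in-degree + 1. The +1 offset is
  required so nodes without incoming edges remain reachable targets; arcs
  point new → old by default, with a flag for the reverse.
* **Shuffled** — directed double-edge swaps (10 × |E| attempts by
  default, rejected if a self-loop or duplicate arc would arise), exactly
  preserving every node's joint (in, out) degree.
* **Shuffled2** — the in- and out-degree sequences are each permuted
  *independently* across nodes before stub-matching realization. The
  independent permutation is the point: it destroys the in/out-degree
  correlation that Shuffled retains, which is exactly the contrast
  between the two models. Stub matching retries on collision and then
  repairs residual conflicts by swapping targets with already-placed
  arcs; unrealizable inputs error with the residual stub count.

Every replicate is seeded as `seed + replicate index`, so an ensemble is
fully determined by its configuration. The observed value's empirical
quantile uses the mid-rank tie rule (strictly-below plus half of ties).
On webs with a planted core, Shuffled ensembles retain systematically
higher mean reachability than Shuffled2 ensembles — hub proteins keep
both high in- and out-degree under Shuffled, which regenerates a core.

## Tissue-specific networks

Expression filtering uses a threshold derived from negative-control probe
intensities: the 0.95 nearest-rank quantile (the `ceiling(0.95·n)`-th
order statistic) of the control A-values. Nearest-rank was fixed over
interpolating definitions because the threshold should be an actually
observed control intensity; the convention is documented rather than
inferred from any one array. Expression is strict (`A > threshold`), so
boundary ties count as not expressed. Proteins absent from the matrix are
treated as not expressed and their count reported. Tissue networks are
induced on the filtered node set first and the largest component is taken
afterwards.

## What the synthetic generator emulates — and what it does not

`generate_web()` plants structure so that recovery can be verified
against ground truth:

* a **core** of `core_size` proteins: `n_bridges` inhibitor *bridges*
  plus protease groups that are internally cyclic but connect to each
  other *only through the bridges* (every group cleaves every bridge —
  serpin-bait or trap-bait cleavages — and every bridge inhibits one
  member of every group). Any single surviving bridge keeps the core
  strongly connected; removing all of them fragments it. This is the
  redundancy pattern behind the "remove all six vs. any five of six"
  contrast in the perturbation suite;
* **cascades** — directed zymogen-activation chains whose terminal
  proteases cleave the bridges, placing cascade members in the upstream
  tier;
* **downstream proteases** activated by the core that cleave only plain
  substrates, populating the low-reachability mode;
* heavy-tailed substrate out-degrees from a truncated discrete power law
  (default exponent 1.8, chosen so the top decile of proteases holds the
  majority of cleavages, reflecting the extreme annotation concentration
  in curated degradome data);
* independent relevance labels (60% `yes` by default) and class labels
  from a metallo/serine-dominated mix.

Peripheral (non-bridge) inhibitors receive cleavages only from cascades,
never from the core — otherwise they would silently reconnect the core
groups and dissolve the planted bridge redundancy. Defaults (120
proteases, 30 inhibitors, 150 substrates, core 48 with 6 bridges, 4
cascades of length 8) give a ~150-node largest component with a strongly
bimodal reachability distribution.

The generator is scenario-based, not a fit: it reproduces the *shape* of
a curated snapshot (bimodality, degree skew, class structure, relevance
labels) but not its annotation biases, its many-to-many ortholog
structure, or any kinetic realism. Tests passing on synthetic webs
therefore demonstrate correctness of the algorithms and the qualitative
orderings (bridge dependence, Shuffled vs. Shuffled2, connector-AUC
correlation), not quantitative agreement with any database snapshot.

Bimodality of a reachability distribution is declared when the largest
gap between consecutive observed values spans at least 25% of the
reference node count with at least 15% of nodes on each side; the gap
criterion deliberately rejects the uniform spread of a pure cascade.

All randomness flows from one master seed through derived sub-seeds
(topology, labels, expression), so each stage reproduces independently.

## Numerical and degenerate-input choices

* Components and argmax ties break towards the lexicographically
  smallest accession.
* Empty graphs: construction warns and returns a valid empty object;
  component extraction and reachability on zero nodes are errors.
* A single-node largest strongly connected component triggers a warning
  (degenerate core) but tiers are still defined.
* Duplicate input rows collapse to one stored edge with the multiplicity
  reported; referential-integrity failures are errors in strict mode
  (default) and logged drops in lenient mode.
* The canonical edge-list TSV sorts rows lexicographically so exports
  diff bit-exactly; it carries no node annotations, which only the
  GraphML/GML formats preserve.

## Problem sizes used by the test-suite

The property tests run brute-force oracles (transitive closure by
boolean matrix squaring, exhaustive shortest-path enumeration for
betweenness) on graphs of up to 12 nodes, 200 random instances; null
contracts run over 50 seeds; structure recovery over 20 generator seeds
at the default scale; tissue surveys over 24 synthetic tissues. These
sizes make the full suite complete in well under a minute per module
while exercising every code path at the scale where exhaustive oracles
remain exact.

## Known limitations

* Edges are unsigned: paths propose *potential* influence routes whose
  biological sign and relevance require experimental follow-up.
* Overlap counting treats the ortholog map as given; no identifier
  validation or homology inference is performed.
* The generator does not model annotation bias (target/substrate bias)
  and therefore cannot be used to study its effect on connectivity.
* Snapshot-specific quantities from real databases (edge totals, named
  connectors, tissue AUCs) depend on the annotation state at download
  time and are outside what synthetic data can certify.

## A compact end-to-end run

```{r example, eval = FALSE}
tabs <- generate_web(synthetic_web_params(seed = 42))
web  <- build_graph(tabs)
lcc  <- largest_connected_component(restrict_to_protease_web(web))

reachability(lcc)                      # profile, curve, AUC
strongly_connected_core(lcc)           # core membership + tiers
iterative_connector_search(lcc, k = 6) # key connectors
null_experiment(lcc, null_model_config("Shuffled", 500, seed = 1))
```
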