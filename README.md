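# proteaseweb

Graph analysis of protease–inhibitor interaction networks ("protease
webs") in R.

Proteases regulate each other: they activate zymogens, destroy catalytic
domains, and cleave each other's inhibitors. Representing curated
cleavage and inhibition annotations as a directed graph — cleavage edges
protease → substrate, inhibition edges inhibitor → inhibited protease —
turns questions about indirect regulation into questions about directed
paths. This package is for systems biologists who want to quantify that
regulatory potential, find the proteins that hold the network together,
and test whether the observed connectivity survives annotation errors or
tissue-restricted expression.

## What it computes

For a node X, **reachability** is the number of nodes Y (X included)
with a directed path X → Y — the proteins X can potentially influence.
The network-level summary is the **inverse cumulative reachability
curve** F(r) = fraction of nodes with reachability ≥ r and its
normalized area,

    AUC = (1/n) ∫₀ⁿ F(r) dr = mean(reachability) / n,

which equals 1/n for an edgeless network and 1 for a strongly connected
one. Around this core statistic the package provides:

* graph construction from TSV annotation tables, with validation,
  restriction to MEROPS-ID-bearing nodes, component extraction,
  composition and class-interaction summaries, cross-species edge
  overlap, and GraphML/GML/TSV serialization;
* the strongly connected regulatory core, upstream/downstream tiers,
  directed betweenness, shortest-path length histograms, and exhaustive
  shortest-path queries between protein pairs with per-step mechanisms;
* four null ensembles (Erdős–Rényi, preferential attachment forcing the
  observed out-degrees, exact degree-preserving edge shuffling, and
  independent degree-sequence shuffling) with deterministic seeding;
* a perturbation suite: physiological-relevance filtering, removal of
  putative trapping cleavages (serpin / A2M-PZP rule), single and
  combinatorial node knockouts, iterative highest-betweenness connector
  search, and random edge-deletion sweeps reporting worst-case AUC;
* tissue-specific subnetworks thresholded at the 95% nearest-rank
  quantile of negative-control probe intensities;
* a seeded synthetic-data generator that plants a strongly connected
  core, redundant inhibitor bridges, activation cascades and heavy-tailed
  substrate degrees, so every stage is testable without any download.

## Worked example

```r
library(proteaseweb)

tabs <- generate_web(synthetic_web_params(seed = 42))
web  <- build_graph(tabs)
web
#> protease web [full network]
#>   nodes: 300
#>   edges: 904 (832 cleavage, 72 inhibition)

lcc <- largest_connected_component(restrict_to_protease_web(web))
reachability(lcc)
#> reachability profile: 150 nodes, reference n = 150
#>   range [1, 122], mean 59.73, AUC 0.3982

strongly_connected_core(lcc)
#> strongly connected core: 48 nodes, shared reachability 94
#>   upstream 43, downstream 59

iterative_connector_search(lcc, k = 6)
#> iterative connector search
#>   1. IN005 (AUC ratio 0.979)
#>   2. IN003 (AUC ratio 0.877)
#>   3. IN004 (AUC ratio 0.817)
#>   4. IN002 (AUC ratio 0.799)
#>   5. IN006 (AUC ratio 0.781)
#>   6. IN001 (AUC ratio 0.204)

combinatorial_knockout(lcc, tabs$report$bridges)$all_removed
#> perturbation [6 rm]: AUC 0.0811 (20.4% of original); -117 edge(s), -6 node(s)

null_experiment(lcc, null_model_config("Shuffled", replicates = 50, seed = 1))
#> null ensemble [Shuffled], 50 replicates
#>   observed mean reachability 59.73 vs ensemble mean 76.63
#>   empirical quantile of observed: 0.000 (50 replicate(s) exceed it)
```

Reading the numbers: half the 300-protein network is the connected
protease web; its 48-node core members can each influence 94 of 150
proteins. The iterative betweenness search recovers exactly the six
planted inhibitor bridges (`IN001`–`IN006`), and removing all six
collapses the AUC to 20% of the original — while each single removal
leaves most of the connectivity intact, the signature of a redundantly
bridged core. The degree-preserving shuffle attains *higher* mean
reachability than the planted network, showing that high connectivity
emerges readily from these degree sequences.

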