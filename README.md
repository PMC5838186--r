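# ppinet

Topology analysis of protein–protein interaction (PPI) networks and
centrality-based biomarker-panel selection.

## What this package is for

Disease-association queries against interaction databases such as STRING
return a few hundred genes together with confidence-scored, undirected
interactions. A standard way to distil a candidate biomarker panel out of
such an interactome is purely topological:

1. **Centralities.** For every node compute the degree *D*, the normalized
   betweenness centrality *BC* (Brandes' algorithm over unweighted shortest
   paths),

   `BC(v) = [ Σ_{s≠v≠t} σ_st(v) / σ_st ] / ((n−1)(n−2)/2)`,

   and the component-wise closeness *CC(v) = (|C_v|−1) / Σ_{u∈C_v} d(v,u)*
   (isolated nodes score 0 — disease queries typically leave a large set of
   genes with no interactions at the chosen confidence cutoff).
2. **Crucial nodes.** Hubs are nodes with `D > mean + 2·SD` over all node
   degrees; bottlenecks and high-closeness nodes are the top 5 % by *BC* and
   *CC*. The three-way intersection is the **crucial-node set**, the
   candidate biomarker panel.
3. **Clusters.** Overlapping dense modules are grown greedily from seeds by
   maximizing the cohesiveness `f(V) = w_in / (w_in + w_bound + p)` (internal
   versus boundary edge weight, penalty *p* = 2), merged when their match
   coefficient `ω(A,B) = |A∩B|²/(|A||B|)` reaches 0.8, and kept when they
   pass a minimum size (3), minimum density (0.3) and a one-sided
   Mann–Whitney test (in-weights vs out-weights, exact by enumeration up to
   8 members) at `p ≤ 0.001` — the ClusterONE procedure.
4. **Scale-freeness.** The degree histogram *N(k)* is fitted by
   `N(k) = a·k^b` via least squares on log10–log10 values, reporting the R²
   of the log-space regression and the original-scale Pearson correlation.
5. **Enrichment.** A gene set (by default the main cluster; optionally the
   crucial panel) is tested against annotation tables by the right-tailed
   hypergeometric test with BH (or Bonferroni) correction, and redundant
   terms are grouped by Cohen's kappa on their gene-membership vectors
   (threshold 0.4), ClueGO-style.

All of this is implemented here as small composable functions over
[igraph](https://igraph.org/r/) objects, plus a seeded synthetic-benchmark
generator that plants hubs, cliques and enriched terms so that every stage
can be validated against known ground truth.

## Worked example

```r
library(ppinet)

bench <- make_benchmark(synthetic_spec(seed = 7))  # paper-scale benchmark
summarize_graph(bench$graph)
#> Interaction graph: 776 nodes, 2185 edges
#>   density 0.007266, avg clustering 0.1336
#>   components: main 629, 145 isolated node(s), 2 paired node(s)

tab <- centrality_table(bench$graph)   # one D/BC/CC record per node
sel <- select_crucial(tab)
sel
#> Crucial-node selection
#>   degree threshold (mean + 2 SD): 34.88
#>   hubs: 6, bottlenecks: 39, high-closeness: 39
#>   crucial (triple intersection): 5
#>    HUB1, HUB2, HUB3, HUB4, HUB5
```

The five planted super-connected nodes — and nothing else — survive the
triple intersection: one scale-free core node also exceeds the degree
threshold (6 hubs) but is not among both top-5 % centrality sets.

```r
find_clusters(bench$graph)
#> 3 significant cluster(s)
#> Cluster: 8 members, cohesiveness 0.8922, density 1, p = 7.77e-05
#> Cluster: 8 members, cohesiveness 0.8913, density 1, p = 7.77e-05
#> Cluster: 8 members, cohesiveness 0.884, density 1, p = 7.77e-05
```

The three significant clusters are exactly the three planted 8-cliques
(`p = 1/12870`, the exact Mann–Whitney floor for 8-vs-8 full separation).

```r
fit_power_law(degree_histogram(bench$graph))
#> Power-law fit: N(k) = 62.46 * k^-0.9163  (correlation 0.300, R2 on log values 0.333, 26 points)

head(enrich(sel$crucial, bench$annotations), 1)   # planted term ranks first
#>           term k K  p_value p_adjusted group
#> 1 TERM_PLANTED 5 5 4.32e-13   2.16e-12     1
```

The negative exponent is the qualitative scale-free signature; the planted
annotation term tops the enrichment of the crucial panel.

The same analysis runs on real STRING exports:

```r
g   <- read_string_tsv("string_network.tsv", score_threshold = 0.4)
res <- run_pipeline(pipeline_config(input = "string_network.tsv",
                                    out_dir = "results",
                                    annotations = "annotations.tsv"))
```

`run_pipeline()` writes a graph-summary JSON, the centrality table
(Name/D/BC/CC), the selection table with thresholds, the cluster table, the
crucial-node subnetwork as SIF, the degree-distribution fit, the enrichment
and term-network tables, and a run manifest. A thin command-line wrapper
with subcommands `run`, `simulate`, `centrality`, `clusters`, `enrich` and
`fit-degrees` lives at `inst/cli/ppinet.R`.

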