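---
title: "Topology-based biomarker panels from PPI networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-based biomarker panels from PPI networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppinet)
```

## The analysis model

`ppinet` analyzes undirected, confidence-weighted interaction networks of
the kind a STRING disease query returns: a few hundred genes, an edge list
with a combined confidence score, a single dominant connected component and
a long tail of isolated genes. The analysis makes three structural
assumptions, each of which is checked rather than taken on faith:

* **Scale-freeness.** Degree counts follow approximately
  $N(k) \propto k^{b}$ with $b < 0$; most genes interact with few partners,
  a handful are super-connected. The package tests this by fitting the
  degree histogram (see below) instead of assuming it.
* **Topological importance is detectable by centrality.** Hubs (degree),
  bottlenecks (betweenness) and high-closeness nodes carry
  disproportionate control over the network; the candidate biomarker panel
  is their intersection.
* **Functional modules are cohesive.** Dense regions whose internal edge
  weight dominates their boundary weight correspond to protein complexes or
  tightly co-regulated groups.

## Centralities

Shortest paths are *unweighted* hop counts throughout: confidence scores
weight the clustering stage but not path lengths, which matches how the
standard topology tools report degree/betweenness/closeness on interactomes.

* Betweenness is computed by Brandes' single-source accumulation and
  normalized by $(n-1)(n-2)/2$ with $n$ the **total** node count of the
  graph, not the component size. Using total $n$ matches common tool output;
  it means values on a fragmented graph do not reach 1, which is harmless
  for rank-based selection.
* Closeness is computed **within components**:
  $CC(v) = (|C_v|-1)/\sum_{u \in C_v} d(v,u)$, isolated nodes scoring 0.
  On a disease interactome with well over a hundred isolated genes a global
  definition would send every closeness to 0 or near it; the component-wise
  convention keeps main-component closeness in the familiar 0.5–0.65 range
  while still letting isolated genes participate in the ranked pool.
  A side effect worth knowing: every node of an isolated pair has
  $CC = 1$, so tiny components can enter the top-closeness set. The crucial
  set is protected against this by the triple intersection (pair nodes are
  never hubs).
* All per-node outputs are named vectors in byte order, and every ranking
  tie is broken by node id using radix (byte-order) sorting, so results are
  identical across locales and reruns.

## Crucial-node selection

* The hub rule `degree > mean + k·SD` is applied with a **strict**
  inequality, taking the wording of the rule literally; in the
  zero-variance case (regular graph) this makes the hub set empty rather
  than all of the graph, which is the sensible degenerate outcome.
* The SD is the sample SD ($n-1$ denominator) by default; the population
  variant is available (`sd_mode = "population"`). On graphs of several
  hundred nodes the difference is cosmetic, but it is exposed because the
  choice is otherwise invisible in reported results.
* The top-fraction selections keep exactly $\lceil f \cdot n \rceil$ nodes.
  The ceiling guarantees non-empty selections on small graphs; ties are
  broken lexicographically so the selection is a deterministic function of
  the table.
* All nodes — including isolated ones — enter the mean/SD computation and
  the ranked pools, because the analysis is defined on the full retrieved
  gene set, not the main component.

## Cohesiveness clustering

Cluster growth maximizes $f(V) = w_{in}/(w_{in} + w_{bound} + p)$ with
penalty $p = 2$ by default: the penalty models unobserved interactions and
keeps single high-degree nodes from being trivially cohesive. Defaults
(`penalty = 2`, `min_size = 3`, `min_density = 0.3`, `overlap_omega = 0.8`)
follow the published defaults of the cohesiveness-clustering tool this
stage reimplements; the significance cutoff default is `p_threshold = 0.001`.

Design choices where the procedure is underdetermined:

* **Move policy.** From a seed, the single best strictly-improving move
  (add a boundary node / remove a member) is applied until no move
  improves. Candidates are scanned additions-first in byte order of node
  id, and the first best is taken, so growth is fully deterministic. A
  strict improvement requirement (with a $10^{-12}$ float guard) makes
  termination a consequence of monotonicity. The seed itself may be
  expelled: a hub seed whose neighbourhood is not dense typically ends up
  outside the blob grown around it (see *Limitations*).
* **Seeding and coverage.** Seeds are taken in degree-descending order and
  nodes covered by an earlier grown cluster are skipped, bounding the
  number of growths by the number of effectively distinct regions.
* **Significance.** The test compares, across members, each member's
  in-cluster incident weight against its out-of-cluster incident weight by
  a one-sided Mann–Whitney U test. For clusters of at most 8 members the
  p-value is computed by exhaustive enumeration of all
  $\binom{2m}{m}$ rank assignments (midranks for ties); above that, the
  tie-corrected, continuity-corrected normal approximation is used.
* **An exact-test floor worth knowing.** The smallest achievable exact
  p-value for an $m$-member cluster is $1/\binom{2m}{m}$: $1/924 \approx
  0.00108$ for $m = 6$ and $1/3432 \approx 0.00029$ for $m = 7$. A 6-member
  cluster therefore *cannot* pass the 0.001 default cutoff no matter how
  clean its separation; 7 members is the minimum. The test suite probes
  6-clique recovery at `p_threshold = 0.05` for exactly this reason, and
  separately asserts the floor at the default cutoff.
* **Overlap.** Cluster pairs with match coefficient
  $\omega(A,B) = |A\cap B|^2/(|A||B|) \ge 0.8$ are merged (union) until
  stable; overlapping and nested membership among reported clusters is
  permitted and reported as-is.

## Degree-distribution fit

The fit is ordinary least squares of $\log_{10} N(k)$ on $\log_{10} k$ over
the points with $k \ge 1$ and $N(k) \ge 1$ — degree 0 is excluded out of
mathematical necessity, and the logarithm base is immaterial (any base gives
the same $b$ and $R^2$; $a$ is recovered by exponentiation). Reported are
$a$, $b$, the $R^2$ of the log-space regression, and the Pearson correlation
between observed and fitted counts on the original scale. Zero-variance
inputs (all counts equal) yield a flat line with `r_squared_log = 0` and a
warning rather than an error. This is deliberately the least-squares
convention of network-analysis tools, *not* a maximum-likelihood
(Clauset-style) exponent estimate, and no goodness-of-fit hypothesis test is
attempted.

## Enrichment and kappa grouping

Right-tailed hypergeometric tests (via `phyper` on the upper tail, which is
numerically stable for small p) are applied to every term with at least one
query hit; adjustment is Benjamini–Hochberg by default with Bonferroni as
the alternative (the tool this stage is modelled on defaults to a Bonferroni
variant, so both are first-class). Query genes absent from the universe are
dropped with a warning rather than erroring, to tolerate identifier
mismatches. Term redundancy is handled ClueGO-style: Cohen's kappa between
the two terms' gene-membership indicator vectors over the universe, an edge
at $\kappa \ge 0.4$ (default), initial groups from the connected components
of that term graph, and a merge of groups sharing at least half of the
smaller group's terms until stable. Group labels are ordered by each group's
best adjusted p-value. The pipeline enriches the largest significant cluster
by default — the "main cluster" convention — with `enrich_target = "crucial"`
as the override for enriching the biomarker panel itself.

## The synthetic benchmark

`make_benchmark()` generates the study conditions every recovery test runs
under: a preferential-attachment core of 600 nodes with 2 edges per new node
(preferential attachment is used because only scale-freeness, not a growth
mechanism, is assumed), 5 planted hubs each wired to a uniform random 30 %
of the core, three planted 8-cliques each attached by exactly one bridge
edge, 145 isolated nodes and one isolated pair — the component anatomy of a
typical disease query. Edge confidence scores are uniform on $[0.6, 1]$
rounded to 3 decimals: above the conventional 0.4 STRING cutoff, so the
emitted TSV reads back into the identical graph, while still exercising the
weighted clustering and significance paths. Annotations are 50 random terms
of size 5–50 plus one planted term covering the planted hubs. Everything is
a pure function of one integer seed, and regeneration is bit-identical.

What the benchmark does *not* emulate: the empirical density of real STRING
disease networks (a 600-node core with $m = 2$ gives density
$\approx 0.007$, several times sparser than a typical disease interactome),
correlated annotation structure, identifier noise, and any biological
signal. Passing recovery tests therefore demonstrates correctness of the
algorithms on planted structure, not biological validity on real data.

Problem sizes used in the tests were chosen so the full suite runs in well
under a minute of a single CPU: the oracle comparisons use 200 random graphs
of at most 7 nodes (where all simple paths can be enumerated), clique
recovery uses 100-node backgrounds, the scale-free fit check uses a
2000-node preferential-attachment graph, and the end-to-end recovery runs
the full 776-node benchmark twice (for the byte-identity check).

## Limitations

* **Hubs and cohesive clusters are antagonistic on sparse graphs.** A node
  wired to 30 % of a sparse core has enormous boundary weight; greedy
  cohesiveness growth will expel it from any small cluster, and any large
  cluster containing it fails the 0.3 density filter (a 100-node cluster at
  density 0.3 needs ~1500 internal edges, more than half of the whole
  benchmark's edge budget). On this package's benchmark the significant
  clusters are exactly the planted cliques and the crucial hubs belong to
  none of them. Observing the crucial panel *inside* the main cluster —
  as real, much denser disease interactomes show — requires a dense core
  the benchmark deliberately does not fake. The acceptance suite asserts
  the containment property anyway and documents its failure here as an
  honest negative: it is a property of dense interactomes, not of
  scale-free graphs with randomly wired super-hubs in general.
* Published crucial-node tables produced by GUI tools sometimes print
  coarsely quantized betweenness values; no attempt is made to reproduce
  any particular tool's display rounding — the table schema, not its
  binary-identical values, is the contract.
* The exact Mann–Whitney floor (above) caps attainable significance for
  small clusters; interpret `p_threshold` jointly with `min_size`.
* Centralities are unweighted by design; no weighted-shortest-path,
  eigenvector or stress centralities are offered.
* No live database access, identifier mapping, ontology propagation or
  figure rendering: inputs are plain files, outputs are plot-ready tables.
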