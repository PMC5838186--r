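Package: ppinet
Title: Topology Analysis of Protein-Protein Interaction Networks and
    Biomarker Panel Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for undirected, confidence-weighted
    protein-protein interaction (PPI) networks of the kind exported by the
    STRING database. Computes degree, betweenness (Brandes) and
    component-wise closeness centralities; selects hub (mean + k*SD degree),
    bottleneck (top-fraction betweenness) and high-closeness nodes and
    intersects them into a crucial-node biomarker panel; detects significant
    overlapping dense clusters by cohesiveness-greedy growth with a
    one-sided Mann-Whitney significance filter (ClusterONE-style); fits a
    power law to the degree distribution by least squares on logarithmized
    values; and performs hypergeometric term enrichment with Cohen's-kappa
    term grouping (ClueGO-style). Includes a seeded synthetic benchmark
    generator with planted hubs, cliques and enriched terms, and a
    configuration-driven pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
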