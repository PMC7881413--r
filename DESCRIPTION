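Package: netprio
Title: Gene Prioritization by Topological Analysis of Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for prioritizing disease genes from case/control
    expression data by protein-protein interaction (PPI) network topology.
    Genes are ranked by differential expression (Welch t-test, fold-change and
    p-value filters), mapped onto a confidence-weighted interaction database,
    augmented with their strongest first neighbors, and scored on the main
    connected component by degree and exact Brandes betweenness centrality.
    Hubs, bottlenecks and hub-bottlenecks are called by a top-decile rule, and
    the resulting crucial genes are enriched against GMT annotation term sets
    with a hypergeometric test, Benjamini-Hochberg correction and kappa-score
    clustering of redundant terms. A synthetic-data module generates
    fully-labeled expression matrices, interaction databases and annotation
    collections emulating a two-group (20 vs 20) transcriptomic study of
    Crohn's disease, so the whole workflow runs and is validated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
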