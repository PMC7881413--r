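# netprio

Gene prioritization by topological analysis of protein–protein interaction
(PPI) networks, for transcriptomic case/control studies — modeled on the
workflow used to nominate GATA3 and six other crucial genes in pediatric
Crohn's disease from a 20-patient vs 20-control expression profile.

Given (i) a genes × samples expression matrix with a two-group sample map,
(ii) a STRING-dialect interaction edge list (`node1 node2 combined_score`,
scores 0–1000), and (iii) annotation term sets in GMT format, the pipeline:

1. **Differential expression.** Per-gene Welch t-test on log2 values;
   effect `log2FC = mean(case) − mean(control)`, two-sided fold change
   `FC = 2^|log2FC|`; genes ranked by p-value, the top 250 kept, and
   significant DEGs flagged by `FC > 2` and raw `p ≤ 0.05` (BH-adjusted q
   reported alongside).
2. **Network construction.** Significant DEGs are mapped onto the
   interaction database (default confidence ≥ 400); unrecognized genes are
   reported. The sparse seed network is augmented with the top *m* = 20
   first neighbors, ranked by (distinct query connections, summed
   confidence, id), and the main connected component is extracted, shedding
   isolated query genes. A scale-free diagnostic (least-squares fit of
   log10 P(k) vs log10 k) is reported before and after augmentation.
3. **Centrality.** Degree K and exact betweenness centrality
   `BC(v) = Σ_{s≠v≠t} σ_st(v)/σ_st · 2/((n−1)(n−2))` (Brandes' algorithm,
   unweighted shortest paths, Network-Analyzer normalization) on the main
   component.
4. **Classification.** Hubs = top `⌈0.10 · n_query⌉` query genes by K;
   bottlenecks = same by BC; crucial genes = their union; hub-bottlenecks =
   their intersection.
5. **Enrichment.** Hypergeometric over-representation of the crucial genes
   against GMT terms (`p = P[X ≥ k]`, `X ~ Hypergeom(N, K_term, n_query)`),
   BH correction, and grouping of significant terms into clusters by
   Cohen's kappa ≥ 0.4 on their gene memberships.

A synthetic-data module (`sim_config()`, `simulate_expression()`,
`simulate_database()`, `simulate_annotations()`, `simulate_study()`)
generates fully labeled fixtures emulating the study design — 20+20
samples, 81 planted DEGs with |log2FC| ∈ [1.2, 3], 69 of them recognized by
the database, 39 connectable through 20 designated neighbors — so the whole
workflow runs and is validated without any download.

## Worked example

The analysis workflow lives in `analysis/01_simulate.R` …
`analysis/05_enrichment.R`; each stage is a thin driver over the package
functions and writes its tables under `results/`. Running them in order
prints, among other things:

```
significant DEGs (FC > 2, p <= 0.05): 81
planted DE genes recovered: 81/81; false flags: 0
query genes: 81; recognized by the database: 69 (85.2%)
seed network verdict: not scale-free (weak interactions)
first neighbors added: 20
isolated query genes excluded: 30
main connected component: 59 nodes
augmented network verdict: scale-free-like (slope -1.14, r^2 0.72)
query genes in component: 39 -> top decile k = 4
planted target GENE0312 called hub-bottleneck: TRUE
```

i.e. of 2000 simulated genes, 81 pass the fold-change/p-value filter; 69
are recognized by the interaction database; after adding 20 first neighbors
and dropping 30 isolated query genes, the 59-node main component carries 39
query genes, the top decile (4 genes) by degree and by betweenness are
called hubs and bottlenecks, and the planted maximal-centrality gene is
recovered as a hub-bottleneck.

Stage 4 also applies the classification rule to the packaged reference
table of the seven crucial Crohn's disease genes
(`reference_centrality_fixture()`):

```
Crucial genes: 7 (hubs 4, bottlenecks 4, hub-bottlenecks 1)
  hub-bottleneck: GATA3
  node_id  K    BC is_hub is_bottleneck is_hub_bottleneck rank_by_K rank_by_BC
1   GATA3 28 0.038   TRUE          TRUE              TRUE         1          3
2    IL-7 26 0.007   TRUE         FALSE             FALSE         2          5
...
```

GATA3 (K = 28, BC = 0.038) is the unique gene in both top-decile lists, and
the union of hubs {GATA3, IL-7, CD28, CD5} and bottlenecks {TXN, ETS-1,
GATA3, CCR7} has size seven. Stage 5 enriches those seven genes against a
planted 3-block annotation catalogue and recovers all 18 block terms as
significant, grouped back into the 3 planted kappa clusters.

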