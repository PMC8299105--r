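# fungalnet

Who shapes a soil fungal community — the few taxa found everywhere, or the
many confined to one habitat? `fungalnet` implements the complete inference
chain behind that question for OTU count tables spanning several
bioclimatic regions:

1. **Niche-breadth classification.** For OTU *j* with read fractions
   *P<sub>ij</sub>* across *N* samples, Levins' index
   *B<sub>j</sub> = 1 / Σ<sub>i</sub> P<sub>ij</sub>²* ranges from 1
   (single-sample) to *N* (even spread). Generalists combine high global
   *B* (> 17), broad occurrence (> 50% of samples) and non-negligible mean
   relative abundance (≥ 2×10⁻⁵); habitat specialists have low
   within-region *B* (< 12 or 17 by region) with more than four
   within-region occurrences. Data-driven thresholds via Tukey outlier
   fences are available.
2. **Ensemble co-occurrence network.** Five association measures (Pearson,
   Spearman, Bray–Curtis, symmetrised Kullback–Leibler, mutual
   information) with a shared permutation null, ≥ 2-measure
   direction-consistent support, Brown's dependent p-value combination,
   Benjamini–Hochberg control (α = 0.001) and bootstrap stability.
3. **Topology.** Degree, component-scaled closeness, betweenness,
   eigenvector centrality, Louvain modules, Zi–Pi node roles,
   B-versus-centrality regressions, and the one-way ANOVA (+ Tukey
   letters) contrasting degree across niche groups.
4. **Driver path analysis.** Standardized direct and total effects of
   spatial/climatic/edaphic variables over a declared DAG
   (observed-variable path analysis with PCA composites and bootstrap
   significance).
5. **Synthetic communities.** A generator with planted generalists,
   region-restricted specialists, correlated OTU blocks (true edges) and
   known path coefficients, so every stage is testable end to end.

## Worked example

```r
library(fungalnet)

sim <- generate_community(synthetic_spec(seed = 42))
sim$table
#> OTU table: 430 OTUs x 180 samples, 1800000 reads

cl <- niche_classify(sim$table, sim$metadata)
cl
#> Niche-breadth classification over 430 OTUs and 180 samples
#>   generalist B > 17 | occurrence > 50% | mean relabund >= 2e-05
#>   specialist B < subtropical = 12, warm_temperate = 17, temperate = 17 | region occurrence > 4
#>
#>                generalist                    medium    specialist:subtropical
#>                        20                       320                        30
#>      specialist:temperate specialist:warm_temperate
#>                        30                        30
```

On this draw every planted generalist, specialist and medium is recovered
exactly (borderline mediums occasionally land in a specialist class; across
seeds specialist precision stays near 0.99). The network stage finds the
planted correlated blocks and little else:

```r
net <- infer_network(sim$table,
                     network_config(n_permutations = 100,
                                    n_bootstraps = 100, seed = 42))
net
#> Ensemble co-occurrence network: 430 nodes, 43 edges
#>   92235 pairs tested, 6459 passed the >=2-measure screen; alpha = 0.001 (BH on Brown-merged p)
#>   directions: 35 positive / 8 negative

topo <- network_topology(net, cl, seed = 1)
round(summary(topo)$mean_degree_by_label, 2)
#>                generalist                    medium    specialist:subtropical
#>                      2.60                      0.03                      0.13
#>      specialist:temperate specialist:warm_temperate
#>                      0.40                      0.27
```

Planted generalists (hosting the correlated blocks) out-connect every
other group — the mean-degree contrast that motivates calling generalists
network hubs. Driver effects are recovered from synthetic path data:

```r
dag <- default_path_dag()
dat <- generate_sem_dataset(dag, n = 5000, seed = 1)
fit <- fit_paths(dat, dag[c("from", "to")])
round(coef(fit), 2)
#>          space -> climate     climate -> generalist     climate -> specialist
#>                      0.72                      0.20                      0.46
#>     edaphic -> generalist     edaphic -> specialist generalist -> coexistence
#>                      0.24                      0.40                      0.28
#> specialist -> coexistence    climate -> coexistence
#>                      0.15                      0.24
```

(planted values 0.70, 0.20, 0.45, 0.25, 0.40, 0.30, 0.15, 0.25 — every
fitted coefficient lands within 0.05 of its target).

A pipeline wrapper (`run_pipeline()` or the `inst/scripts/fungalnet`
command line: `simulate | classify | network | topology | effects | run`)
sequences all stages, writes TSV/GraphML outputs and a JSON manifest with
all parameters and derived seeds; identical seeds give byte-identical
outputs.

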