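---
title: "Niche breadth, co-occurrence networks and driver path effects"
author: "fungalnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche breadth, co-occurrence networks and driver path effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fungalnet)
```

# The analysis chain

`fungalnet` implements the inference chain used to ask whether generalist
taxa structure a soil fungal community: classify OTUs into generalists,
habitat specialists and a medium remainder via Levins' niche breadth; infer
a co-occurrence network from an ensemble of five association measures with
permutation support; characterise the network roles of each group; and
estimate standardized total effects of spatial, climatic and edaphic drivers
over a declared acyclic path diagram. A synthetic community generator with
planted ground truth makes every stage falsifiable without external data.

# Niche breadth and classification

For OTU $j$ with counts $n_{ij}$ over $N$ samples, the profile
$P_{ij} = n_{ij} / \sum_i n_{ij}$ is the fraction of the OTU's reads in
sample $i$, and Levins' niche breadth is

$$B_j = \frac{1}{\sum_{i=1}^{N} P_{ij}^2},$$

ranging from 1 (all reads in one sample) to $N$ (a perfectly even spread).
$B_j$ can never exceed the number of occupied samples, which makes it a
joint abundance-evenness-occupancy measure. Note the within-OTU
normalisation: only this reading makes $B$ comparable to thresholds near 17
on a ~200-sample design ($B \in [1, N]$); the within-sample normalisation
is used solely for the mean-relative-abundance filter.

The default rule set (all inequalities strict):

* **generalist** — global $B > 17$, occurrence in more than 50% of samples,
  and mean within-sample relative abundance of at least $2\times10^{-5}$;
* **habitat specialist** — within-region $B$ (profile renormalised over the
  region's samples) below the region threshold (12 for subtropical, 17 for
  warm temperate and temperate) and within-region occurrence above 4;
* **medium** — everything else that passes the abundance filter;
  `filtered` marks OTUs below it that meet no specialist rule.

The fixed thresholds correspond to Tukey outlier fences of the B
distribution of a ~3,800-OTU, ~200-sample multi-region cropland survey;
`suggest_outlier_threshold()` recomputes such fences, and
`auto_threshold = TRUE` switches the classifier to them, which is the
appropriate mode for data of very different dimensions. Generalist takes
precedence when both rules fire; an OTU qualifying as a specialist in
several regions is assigned the lowest-B region, with ties recorded. The
abundance filter is applied to the generalist rule only, where it is
stated; applying it to the specialist rule as well would only relabel a
handful of `filtered` OTUs.

# Ensemble co-occurrence network

For every OTU pair that passes the prevalence filter (at least 4
occurrences and 10 reads), five association measures are computed: Pearson
and Spearman correlation, Bray-Curtis dissimilarity, symmetrised
Kullback-Leibler divergence on pseudocounted, normalised vectors (default
pseudocount 1 before normalisation), and mutual information on
equal-frequency-binned abundances ($\lceil\sqrt{n}\rceil$ bins, capped at
10).

**Null model.** All measures share one stream of sample-order permutations
per network (default 1,000). The p-value of a measure is the two-sided tail
probability of its deviation from the permutation-null mean. Three ways of
turning the null sample into a tail probability are provided
(`p_method`):

* `"pooled"` (default): each pair's null scores are standardized by that
  pair's null mean and sd and the standardized deviations are pooled across
  all pairs per measure. The p-value resolution becomes
  $1/(\text{pairs}\times\text{permutations})$ instead of
  $1/\text{permutations}$, which is what allows edges to survive
  Benjamini-Hochberg control at $\alpha = 10^{-3}$ with a finite
  permutation budget, while the (typically heavy) tail of the null is still
  estimated from the data rather than assumed. The cost is an assumption of
  approximate shape homogeneity of the standardized nulls across pairs.
* `"empirical"`: the exact per-pair count-based p,
  $(1 + \#\{\text{null at least as extreme}\})/(B+1)$. Fully assumption-free
  but floored at $1/(B+1)$: with a few hundred permutations no edge can
  reach a BH-adjusted $10^{-3}$, so this mode is for calibration studies,
  not production inference.
* `"gaussian"`: a normal tail on the per-pair z-score. Anti-conservative
  for heavy-tailed count data; provided for comparison.

**Measure-tie handling.** Mutual information uses tie-collapsing quantile
breaks: equal values always share a bin, so the (often numerous) zeros of a
count vector fall into one bin. Breaking ties by sample order instead
couples the zero patterns of the two vectors through their shared ordering
and manufactures association for every zero-heavy pair — a subtle artifact
we observed to dominate all genuine signal on realistic tables.

**Edge calling.** A pair becomes a candidate when at least `min_support`
(default 2) measures have raw p below 0.05 and all supporting measures
agree in direction (correlation sign; dissimilarity below the null mean
means co-presence; sign-blind mutual information borrows the Spearman
sign). Disagreeing supporters discard the pair. Candidate p-values are
merged with Brown's method using the covariance of the $-2\log p$
statistics estimated from the shared permutation stream (pseudo p-values
of each replicate within the null, diagonal rescaled to 4), so that the
near-duplicate information in, say, Pearson and Spearman is not
double-counted; with independent measures the merge reduces exactly to
Fisher's method. Benjamini-Hochberg control is applied across the
candidate family — the ensemble analogue of CoNet's pre-selected
candidate-edge family — at $\alpha = 0.001$, and surviving edges must
finally be bootstrap-stable: at least `min_support` of the supporting
measures must have a central 95% bootstrap percentile interval (default
1,000 resamples) that excludes the permutation-null mean. Resamples that
collapse a vector to a constant are skipped; a measure with more than half
degenerate resamples counts as unstable.

The optional `min_consensus_score` filter (a floor on the absolute
correlation-family score) mirrors the "robust" edge threshold sometimes
shown alongside such networks; it is off by default because its exact
semantics vary between reports.

# Topology

`network_topology()` reports per node: degree; component-scaled closeness
$\frac{k-1}{\sum d}\cdot\frac{k-1}{n-1}$ (comparable across the
disconnected components typical of co-occurrence graphs; isolated nodes
get 0); betweenness normalized by $(n-1)(n-2)/2$; eigenvector centrality
(dominant adjacency eigenvector, max-normalized, computed on the full
graph by default with a per-component option); Louvain modules at
resolution 1 (deterministic under a seed); and the Guimerà-Amaral role
coordinates $Z_i$ (within-module degree z-score) and $P_i$ (participation
coefficient) with the standard cutoffs 2.5 and 0.62 for module hubs,
connectors, kinless nodes and peripherals. `b_centrality_regressions()`
reproduces the B-versus-closeness/betweenness ordinary least squares
fits, and `compare_degree_groups()` runs the one-way ANOVA over niche
groups with Tukey HSD letters (the post-hoc behind the letter display is
not named in the source; Tukey is the conventional choice).

# Driver path analysis

The covariance-based structural equation stage is reduced to
observed-variable path analysis on a user-declared DAG: all variables are
z-scored, every endogenous node is regressed on its parents by ordinary
least squares, and the standardized total effect of any source on any
target is the path-sum of coefficient products, computed as
$(I-A)^{-1}$ in topological order. Composite variables (e.g. a carbon
block from SOC and DOC) are the sign-aligned first principal-component
score of their indicators — an approximation to the composite handling of
covariance-based SEM software. Model fit indices are out of scope;
per-node $r^2$ is reported instead, and edge/total-effect significance
comes from a row-resampling bootstrap (two-sided add-one smoothed p).

`generate_sem_dataset()` draws data in topological order with `"auto"`
noise (one minus the explained variance), so every node is unit-variance
and planted coefficients are directly comparable to fitted standardized
ones.

# The synthetic community generator

`generate_community()` draws, for a configurable region design (default
three regions of 60 samples at depth 10,000):

* **base abundances** from a lognormal with $\sigma = 1.5$, assigned by
  rank: generalists receive the heaviest weights (matching the empirical
  observation that a handful of generalists holds over a third of all
  reads), specialists the next tier, mediums the remainder floored at the
  lognormal median so that their designed occupancy is not erased by
  sampling;
* **occupancy masks**: generalists occupy 95% or more of all samples;
  specialists exactly 8 samples inside one region and zero outside;
  mediums a uniform fraction in 0.40-0.50, stratified so every region
  carries the same count. The band is deliberately placed inside the
  "medium" region of the classification rules — a planted archetype whose
  truth label the correct procedure cannot recover would make recovery
  tests meaningless — and the stratification removes habitat signal from
  mediums, so the planted correlation blocks are the only planted network
  structure;
* **per-sample variation**: multiplicative lognormal jitter with sd 0.3;
  members of each planted block replace their jitter with draws from an
  exchangeable multivariate normal (sd 1, correlation `rho`, default two
  five-OTU blocks at 0.8) hosted on the lightest generalists so the
  planted swings do not move a large share of each sample's reads
  (top-weight hosts would induce compositional common-mode correlation
  across the whole table);
* **counts** by per-sample multinomial sampling at fixed depth, mimicking
  a rarefied table; column sums equal the depth exactly.

What the generator does **not** emulate: taxonomic structure, sequencing
error, batch effects, distance-decay within regions, and the full
compositional coupling of dominant taxa (jitter on the heavy generalists
is kept moderate). Passing recovery tests therefore demonstrates
correctness of the inference chain under a controlled model, not
performance guarantees on arbitrary real data.

# Numerical choices and degenerate inputs

Rarefaction subsamples without replacement (the convention when the target
depth is below every retained sample's total) and drops samples below the
target depth. Constant vectors make the correlation measures undefined;
such measure values are excluded from support rather than zero-filled. A
p-value of exactly 0 entering Brown's merge is clamped to the machine
minimum with a warning. Quartiles use linear interpolation (R type 7).
Louvain module detection and all permutation/bootstrap machinery are
deterministic under the configured seeds; the pipeline derives per-stage
seeds from one master seed by stage-name hashing so stages can be rerun
independently. Problem sizes used by the packaged validation suite --
e.g. 200-permutation networks on 60 x 100 tables, a 430-OTU / 180-sample
reference community at 100 permutations, and n = 5,000 path-model draws --
were chosen so the whole suite re-runs comfortably on a laptop while
keeping Monte-Carlo margins far from the asserted bounds.

# Known limitations

* The pooled null assumes standardized-null shape homogeneity across
  pairs; strongly heterogeneous pair families (e.g. mixing presence
  patterns with radically different sparsity) retain a mild tail
  inflation (about a factor two at $p = 10^{-3}$ in our checks), which the
  support, merging, BH and stability stages jointly absorb.
* Compositionality is only partially addressed: permutations preserve
  per-pair marginals but not the simplex constraint; dominant-taxon
  common-mode effects can induce edges in extreme settings.
* Observed-variable path analysis ignores measurement error in composites
  and reports no global fit statistics.
* The classifier's fixed thresholds are design-specific; use
  `auto_threshold` for other dimensions.
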