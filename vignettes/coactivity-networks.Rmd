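---
title: "Co-activity networks and dysbiosis in the honeybee gut: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-activity networks and dysbiosis in the honeybee gut: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beenet)
library(dplyr)
```

## The problem

Honeybees (*Apis mellifera*) carry a compact, well-characterised gut
microbiota: four core phylotypes found in every worker (*Lactobacillus*
Firm-4/Firm-5, *Bifidobacterium*, *Gilliamella apicola*, *Snodgrassella
alvi*), a handful of non-core members (*Frischella perrara*, *Bartonella
apis*, *Parasaccharibacter apium*) and a tail of low-abundance taxa.
Sublethal exposure to neonicotinoid insecticides such as clothianidin
perturbs this community; supplementing exposed bees with candidate
beneficial strains (*Enterobacter*, *Pantoea*) may partially restore it.

`beenet` implements the analysis used to quantify such dysbiosis from
16S rRNA *transcript* counts (a proxy for functional activity rather than
mere presence): per-condition signed co-activity networks, their topology,
differential taxon activity between conditions, and cage-cohort survival.
Because raw sequencing data are not needed to validate the statistical
machinery, the package ships a synthetic-data generator that reproduces the
experiment's replicate structure, and every stage is tested end to end
against it.

## Data model

Everything is tabular. An *activity table* is a wide tibble (`taxon_id`
plus one integer count column per sample); sample metadata (condition, gut
section, cage, replicate) travels in a companion tibble. The experimental
design being emulated is six groups (sugar control, pesticide control, two
supplementation controls, two curative groups), three gut sections
(midgut, ileum, rectum), six replicate samples per condition — five pooled
workers per replicate, two replicates per cage across three cages — and a
28-day mortality follow-up with 3 cages x 200 bees per group.

## The synthetic community generator

`gen_activity_table()` draws counts through a Gaussian copula: a
multivariate normal sample with a *latent correlation matrix*, mapped
through the standard normal CDF and inverted through per-taxon
negative-binomial quantile functions. Marginals are NB(mu, alpha) with
variance mu + alpha * mu^2 — the standard parameterisation for
overdispersed 16S counts — and planted latent correlations surface as
rank (Spearman) correlations between taxa, which is exactly what the
network stage estimates.

Numerical choices:

* User edge plans are rarely exactly positive semi-definite. The latent
  matrix is repaired by eigenvalue clipping at 1e-10 and rescaled to unit
  diagonal, with a warning; if the repair moves any planted entry by more
  than 0.1 the generator refuses and names the offending pair, because the
  user's plan would no longer be what is simulated.
* Mean abundances default to a log-uniform draw between 10 and 20,000
  transcripts. The abundance distribution of real gut taxa is not fixed by
  the study design, so the default is deliberately loose (a few dominant
  taxa over a long tail) and fully overridable.
* Per-taxon dropout (zero inflation) is available to emulate occurrence
  gaps but defaults to 0.
* Survival times are whole days (geometric daily death probability
  `1 - exp(-hazard)`), matching daily mortality recording; cage effects are
  lognormal frailties on the hazard, default SD 0.2 — enough to make cages
  visibly heterogeneous without overwhelming a hazard ratio of 3.

What the generator does **not** emulate: read-level sequencing noise,
ASV inference, chimeras, or compositional sampling of a fixed sequencing
depth (counts are drawn per taxon, not allocated from a library-size
total). Passing tests therefore validate the statistical machinery, not
the upstream bioinformatics.

## Taxonomy rules

`assign_taxonomy()` applies two rules: a hit with percent identity
strictly above 98 assigns its full path at species rank ("above 98%" is
read literally, so ties at exactly 98.0 fall through); otherwise the
lineage is the lowest common ancestor — the longest shared rank prefix —
of the top 50 hits. No MEGAN-style min-score or top-percent prefilter is
applied by default (the `lca_top_percent` argument provides the knob).
Paths use a fixed 7-rank ladder so prefix comparison stays rank-aligned.
Membership classification matches genera case-insensitively against the
core and non-core lists above.

## Inclusion rules and the occurrence = 3 gap

Per condition, taxa occurring in more than 3 of 6 replicates are
*included*; taxa below 0.01% mean relative activity occurring in fewer
than 3 replicates are *low-activity*. The verbatim rules leave occurrence
exactly 3 unaddressed: such taxa are retained for correlation but labelled
`"borderline"`, so no data are silently dropped. Low-occurrence but
high-activity taxa fit neither rule and are excluded. Mean relative
activity is computed per sample (share of the sample total) and averaged
over the condition's replicates, zeros included; the same statistic is the
node-size attribute in network exports.

## Network inference

For every taxon pair, Spearman's rho on average-ranked profiles. P-values:

* n <= 8 replicates: **exact two-sided permutation p** by full enumeration
  of all n! permutations of one margin (720 at the study's n = 6). Ties
  are handled exactly because tied ranks are permuted as-is.
* n > 8: the t approximation with n - 2 degrees of freedom. The exact
  two-sided p at n = 8 is discrete with point masses up to ~0.05, so no
  continuous formula can track it uniformly closer than ~0.026; measured
  against the *mid-p* of the permutation distribution (the quantity a
  continuous approximation estimates), the t path agrees within 0.013 over
  the full null support at n = 8.

Constant (all-tied) taxa have no defined rank correlation and are dropped
with a warning. q-values are Benjamini-Hochberg over all pairs of one
(condition, gut section) family — networks are built per condition per
section, twelve in the emulated design.

Edges are kept when |rho| >= 0.4 **and** the significance gate passes.
The published selection rule is stated once as raw p < 0.05 and once as
FDR-adjusted p < 0.05; the package gates on the FDR-adjusted q by default
(`gate = "fdr"`), matching the description of the published networks, with
`gate = "raw"` available. Edge sign is the sign of rho; *modules* are
connected components among interacting nodes (the term is not formally
defined in the source analysis; community detection such as Louvain is
deliberately out of scope).

At the study's own scale (n = 6, ~15 genera), the FDR gate is severe: the
smallest achievable exact p is 2/720 ≈ 0.0028 and the BH family has ~105
pairs, so only densely supported planted structure survives. This is real,
and the package reports it rather than hiding it: the acceptance script
recovers planted |rho| = 0.9 edges with precision and recall ~1.0 at
n = 50 replicates and recall ~0 at n = 6. Published networks built from
many more ASV-level taxa have much larger BH families and correspondingly
more admissible edges.

### Compositionality

Correlating per-sample *relative* activities introduces closure: with few
genera and a handful of dominant taxa, ratios share denominators and
spurious strong correlations appear. Measured on the synthetic community,
scoring planted count-scale edges from relative-activity profiles drops
precision from 1.0 to ~0.35 at n = 50. The pipeline follows the published
method (correlations on relative activity by default; raw counts are one
argument away), and this caveat applies equally to any Spearman
co-abundance network. Compositionality-aware estimators (SparCC,
SPIEC-EASI) are an explicit non-goal.

## Topology

`node_metrics()` follows Cytoscape NetworkAnalyzer conventions: degree DG
(incident edges, signs ignored), closeness centrality CC as the reciprocal
of the mean shortest-path distance within the node's connected component,
and neighborhood connectivity NC as the mean degree of neighbors. Only
interacting nodes (degree >= 1) exist in a network, so no isolated-node
convention is needed.

`compare_topology()` pools node-level values across conditions and runs a
tie-corrected Kruskal-Wallis omnibus test plus pairwise Dunn z tests
(tie-corrected SE, two-sided normal p). The source analysis does not state
its pairwise adjustment; the default here is BH across the pair family,
switchable to Bonferroni or none. The statistical unit is the node, as in
the published violin plots — this is pseudo-replication (nodes of one
network are not independent), acknowledged rather than "fixed".

## Differential activity

A deliberately simple, fully specified negative-binomial Wald test in the
DESeq2 mould, because downstream use needs only the sign and the
adjusted-significance call per taxon. Median-of-ratios size factors
(medians taken on the log scale); pooled method-of-moments dispersion
`alpha = (var - mu)/mu^2` floored at 1e-8; delta-method SE of the log2
fold change; BH across tested taxa. A pseudo-count of 0.5 enters the
*reported* fold change only, so structural zeros stay finite without
biasing the test. The Wald statistic is referred to a t distribution with
n1 + n2 - 2 degrees of freedom: with a plug-in dispersion at the study's
6-vs-6 scale a normal reference is visibly anticonservative (~0.09
measured type-I at nominal 0.05, vs ~0.05 with the t reference). DESeq2's
trended-dispersion and fold-change shrinkage are intentionally not
reproduced.

## Survival

`km_estimate()` is the product-limit estimator with Greenwood variance and
a log-scale confidence band; same-day deaths are simultaneous and
horizon survivors are censored. Group comparison is the two-sided log-rank
test per pair with BH across pairs; a stratified variant pools
observed-minus-expected within strata. The published analysis fitted a
Cox mixed-effects model with cage as a random effect and Tukey-adjusted
contrasts; frailty-model estimation is a large sub-project orthogonal to
the network methods, so it is replaced here by the (optionally stratified)
log-rank — note that stratifying by cage is only informative when strata
cross groups, which cages nested in treatment groups do not; the cage
effect is instead represented in the generator's frailty. Bees removed for
sequencing at day 21 would be censored at the sampling day.

## Problem sizes used in validation

The test-suite and acceptance-script simulations are sized to the study
design wherever the design fixes a number (6 replicates, 3 cages x 200
bees, 28 days, hazard ratio ~3) and otherwise to modest Monte-Carlo sizes
chosen for stable estimates: 20 seeds for edge recovery, 1,000 taxa for
the null type-I simulation, 1,000 label permutations for the log-rank
calibration, 100 seeds for survival power, 100 random graphs against the
BFS oracle.

## Known limitations

* Spearman networks inherit compositional artifacts (above) and cannot
  distinguish direct from indirect association.
* The NB Wald stand-in has no dispersion shrinkage; at n = 6 its power is
  below DESeq2's for weak effects.
* Node-level topology comparisons pseudo-replicate.
* The FDR gate at n = 6 with small taxon sets is conservative to the point
  of frequent empty networks; interpret edge counts across conditions, not
  absolute sparsity.
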