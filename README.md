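# beenet

Co-activity network analysis of the honeybee gut microbiota under
pesticide stress and bacterial supplementation.

## What it is for

Sublethal neonicotinoid exposure (e.g. clothianidin at 0.1 ppb in sugar
syrup) perturbs the gut community of *Apis mellifera*; feeding candidate
beneficial strains (*Enterobacter*, *Pantoea*) may partially restore it.
`beenet` is for microbiome researchers who want to quantify that kind of
dysbiosis from 16S rRNA **transcript** count tables (activity, not mere
presence), per gut section (midgut, ileum, rectum) and experimental
condition:

* **Signed co-activity networks.** For each taxon pair, Spearman's rank
  correlation rho across replicate samples; two-sided p-values by **full
  permutation enumeration** when replicates n <= 8 (exactly 720
  permutations at the design's n = 6) and by the t approximation with
  n − 2 df otherwise; Benjamini–Hochberg q over all pairs of one
  (condition, section) family. An edge is kept when |rho| >= 0.4 and
  q < 0.05; its sign is the sign of rho. Modules are connected components.
* **Network topology.** Degree (DG), closeness centrality (CC, reciprocal
  mean shortest-path distance within the component) and neighborhood
  connectivity (NC, mean neighbor degree), compared across conditions by
  Kruskal–Wallis plus pairwise Dunn z tests.
* **Taxonomy.** BLAST-style hit tables resolved by the top-hit rule
  (identity strictly above 98% assigns the hit's species-level path) with
  lowest-common-ancestor fallback over the top 50 hits; genus-level
  core / non-core membership classification.
* **Differential activity.** A fully specified negative-binomial Wald
  test on median-of-ratios normalized counts (log2 fold change, BH
  adjustment) — a transparent stand-in for a DESeq2-style call.
* **Survival.** Kaplan–Meier product-limit curves with Greenwood variance
  and log-rank group comparisons for caged-cohort mortality (3 cages x
  200 bees per group, 28 days).
* **Synthetic data.** A Gaussian-copula negative-binomial generator that
  plants known inter-taxon correlations and cage-structured mortality, so
  the whole pipeline is testable without sequencing data.

## Worked example

Simulate a six-genus community with four planted positive correlations,
infer the network, and inspect it:

```r
library(beenet)

taxa <- c("Lactobacillus", "Bifidobacterium", "Gilliamella",
          "Snodgrassella", "Frischella", "Bartonella")
plan <- tibble::tibble(
  taxon_i = c("Lactobacillus", "Lactobacillus", "Bifidobacterium",
              "Frischella"),
  taxon_j = c("Gilliamella", "Bifidobacterium", "Gilliamella",
              "Bartonella"),
  rho = c(0.86, 0.81, 0.77, 0.80))
design <- community_design(6, taxa = taxa, edge_plan = plan,
                           n_replicates = 50, seed = 2024)
counts <- gen_activity_table(design, "control")
net <- build_network(spearman_matrix(counts),
                     condition = "control", gut_section = "midgut")
net
#> <coactivity_network> control / midgut: 5 interacting taxa, 4 edges (4+, 0-), 2 modules
tidy(net)
#> # A tibble: 4 × 6
#>   taxon_i         taxon_j           rho        p        q sign
#>   <chr>           <chr>           <dbl>    <dbl>    <dbl> <chr>
#> 1 Lactobacillus   Bifidobacterium 0.785 1.44e-11 7.22e-11 +
#> 2 Lactobacillus   Gilliamella     0.807 1.42e-12 2.13e-11 +
#> 3 Bifidobacterium Gilliamella     0.759 1.70e-10 6.38e-10 +
#> 4 Frischella      Bartonella      0.801 2.95e-12 2.21e-11 +
```

All four planted correlations — and nothing else — come back as positive
edges (estimated rho 0.76–0.81 against planted 0.77–0.86), split into the
two planted modules: the core trio and the *Frischella*–*Bartonella*
pair. `Snodgrassella`, planted without partners, is not an interacting
node. Per-node topology:

```r
node_metrics(net)
#> # A tibble: 5 × 5
#>   taxon_id        membership degree closeness_centrality neighborhood_connectivity
#> 1 Bartonella      other           1                    1                         1
#> 2 Bifidobacterium other           2                    1                         2
#> 3 Frischella      other           1                    1                         1
#> 4 Gilliamella     other           2                    1                         2
#> 5 Lactobacillus   other           2                    1                         2
```

Both components are cliques, so every closeness is 1; degree and
neighbor degree separate the trio from the pair. A matching survival
contrast at the study's cohort size (hazard ratio 3 for the pesticide
group, lognormal cage frailty):

```r
d <- survival_design(
  tibble::tibble(label = c("sugar_control", "pesticide"),
                 hazard = 0.004, multiplier = c(1, 3)),
  n_cages_per_group = 3, bees_per_cage = 200,
  cage_frailty_sd = 0.2, horizon_days = 28, seed = 2024)
cohort <- gen_survival_cohort(d)
compare_groups(cohort)
#> # A tibble: 1 × 5
#>   group_a   group_b       statistic        p    p_adj
#> 1 pesticide sugar_control      43.4 4.40e-11 4.40e-11
```

Day-28 survival drops from 0.90 (63/600 deaths) to 0.75 (151/600) and the
log-rank test rejects decisively. `run_pipeline(default_run_config())`
chains all stages — simulate, filter, correlate, build networks, compare
topology, test differential activity, analyse survival — and writes
edge-list/GraphML/SIF/TSV artifacts per (condition, section).

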