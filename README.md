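# methylim

Discovery of immune-related subgroups within a tumor cohort from
promoter DNA methylation, with the downstream immune characterization
that makes the subgroups interpretable.

Array studies of luminal-type tumors show that promoter methylation
carries subgroup structure that expression-based subtyping misses, and
that these subgroups differ in immune infiltration, checkpoint
expression and survival. `methylim` implements the full discovery
pipeline and its verification harness:

* **Differential methylation** — strand-aware promoter windows
  (−2000/+500 bp around the TSS), a strict 50% missingness filter,
  probe-level KNN imputation, per-probe t tests with
  Benjamini–Hochberg FDR and the dual flag |Δβ| ≥ 0.2 ∧ FDR < 0.05.
* **Co-methylation modules** — unsigned weighted correlation network
  a₍ᵢⱼ₎ = |cor(gᵢ, gⱼ)|^β, topological overlap
  TOM₍ᵢⱼ₎ = (Σᵤ a₍ᵢᵤ₎a₍ᵤⱼ₎ + a₍ᵢⱼ₎)/(min(kᵢ, kⱼ) + 1 − a₍ᵢⱼ₎),
  average-linkage clustering of 1 − TOM with a static cut.
* **Module scoring** — hypergeometric pathway enrichment; each module
  scores |KPGenes ∩ Geneᵢ| / |Geneᵢ| where KPGenes pools the genes of
  all significant pathways; key modules must beat the mean score
  strictly and reach the upper quartile.
* **Feature sites** — greedy collinearity pruning (|r| > 0.9), a
  shadow-feature random-forest selector (permuted shadow copies,
  sequential binomial decisions), and a linear SVM scored by
  stratified 10-fold cross-validated and held-out Mann–Whitney AUC on
  a 7:3 split.
* **Key genes and subgrouping** — key-module genes ∩ feature genes;
  Ward clustering of tumors on key-gene promoter means with a
  three-index (silhouette / Calinski–Harabasz / Davies–Bouldin) vote
  for the cluster count; t-SNE for display.
* **Immune characterization** — cell-type signatures from labeled
  single cells (one-vs-rest Wilcoxon markers), ν-SVR deconvolution
  onto the proportion simplex, cytolytic activity
  CYT = (GZMA + PRF1)/2, entropy-based methylation specificity, and
  cohort comparisons (Kaplan–Meier, log-rank, Pearson chi-square,
  Kruskal–Wallis, per-subgroup summary tables).
* **A synthetic cohort generator** that plants all of this structure —
  subgroup-specific promoter hypermethylation organized in
  co-methylation modules, pathway sets enriched for the planted genes,
  labeled single cells, bulk mixtures, subgroup-dependent survival —
  so every stage is testable against ground truth without downloads.

The methods vignette (`vignettes/methylim-methods.Rmd`) documents the
models, the numerical conventions, the generator's design and its
limitations.

## Worked example

```r
library(methylim)

spec     <- luminal_preset("A", seed = 1)      # 40 tumors / 20 normals, k = 2 planted
cohort   <- generate_cohort(spec)
pathways <- generate_pathways(cohort$truth, n_pathways = 20,
                              overlap = 0.8, seed = 1)

fit <- methylim(cohort$beta, cohort$annotation, pathways, cohort$groups,
                min_module_size = 5, seed = 1)
print(fit)
#> Methylation-driven subgroup discovery
#>   40 tumor / 20 normal samples
#>   differential sites: 90 of 500 tested; differential genes: 30
#>   modules: 2 (soft power 6); key modules: turquoise
#>   feature sites confirmed: 79 -> feature genes: 30
#>   key genes: 20
#>   subgroups: k = 2 (C1: 20, C2: 20)

round(summary(fit)$auc, 3)
#>   train      cv heldout
#>       1       1       1
```

Reading: all 90 planted promoter probes are called differential (30
genes); the informative co-methylation modules are selected over the
tumor-wide one; 20 key genes survive the module ∩ feature
intersection; the vote picks k = 2 and the clustering reproduces the
planted subgroups exactly (adjusted Rand index 1.0 against ground
truth). The tumor/normal SVM separates perfectly at this effect size
(Δβ = 0.3), as it should.

Subgroups can then be compared on any cohort artifact, e.g. survival:

```r
clin <- generate_survival(cohort$truth,
                          hazard_by_subgroup = c(S1 = 0.0007, S2 = 0.002),
                          seed = 1)
logrank(clin, fit$subgroups$subgroup[clin$sample_id])
#> chi2 = 12.23, df = 1, p = 0.00047
```

`predict()` assigns new samples to the discovered subgroups by nearest
key-gene centroid; `plot()` draws the seeded t-SNE embedding colored by
subgroup.

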