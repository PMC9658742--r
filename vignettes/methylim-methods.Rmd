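---
title: "Methylation-driven immune subgroup discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-driven immune subgroup discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylim)
```

## The problem

Luminal-type tumors are clinically heterogeneous, and part of that
heterogeneity is epigenetic: promoter DNA methylation separates tumors
into subgroups that differ in immune infiltration, checkpoint expression
and survival. `methylim` implements a complete discovery pipeline for
such subgroups from array beta values, together with the immune
characterization tools (cell-type deconvolution, cytolytic activity,
methylation specificity) and the cohort comparisons (survival, stage,
rank tests) used to interpret them.

The fitting function `methylim()` chains seven stages:

1. **Promoter restriction and QC.** A probe belongs to a gene's promoter
   when it falls in the window from 2000 bp upstream to 500 bp
   downstream of the transcription start, oriented along transcription.
   Coordinates are treated as 0-based and the window half-open on the
   downstream side; a probe exactly at the TSS is always inside. Probes
   missing in more than half the samples are dropped ("more than" is
   strict); remaining holes are filled by probe-level KNN imputation
   (k = 10, root-mean-square distance over commonly observed samples,
   ties broken by probe order). Imputing a complete matrix is the
   identity.
2. **Differential calling.** Per-probe two-sample t test (pooled
   variance by default; Welch available) of tumors versus normals,
   Benjamini–Hochberg FDR over all tested probes, and the dual flag
   |Δβ| ≥ 0.2 and FDR < 0.05, where Δβ is the difference of group mean
   beta values. Zero-variance probes with equal means receive p = 1 so
   the FDR step stays well defined. A gene is differential when at
   least one promoter probe is flagged.
3. **Co-methylation modules.** Over the differential genes' promoter
   means in tumor samples, an unsigned weighted network
   a_ij = |cor|^β is built and converted to the topological overlap
   measure TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j)+1−a_ij).
   Average-linkage clustering of 1−TOM with a static cut at 0.99 of the
   maximum merge height yields modules; clusters below the minimum size
   are left unassigned ("grey") and modules are named by size rank in
   the conventional color order. The soft power defaults to 6, the
   canonical unsigned-network choice: scale-free fitting (which the
   package also implements, with the smallest power reaching a signed
   R² of 0.85, else the best fit) is only meaningful for gene sets in
   the hundreds, not the tens that a desk-scale cohort produces.
4. **Module scoring.** Pathways are tested by one-sided hypergeometric
   enrichment of the differential genes against the collection's
   universe; raw p < 0.05 defines the significant set, without
   multiplicity correction — the selection rule downstream consumes raw
   p values. The genes of all significant pathways are pooled
   (`KPGenes`), and each module scores the fraction of its genes inside
   that pool. A module is a key module when its score strictly exceeds
   the mean score and is at least the upper quartile, with the upper
   quartile computed by the inclusive linear-interpolation convention
   (`quantile(type = 7)`); on scores {0.5, 0.2, 0.8} exactly the 0.8
   module passes. If nothing passes — for instance when all scores tie,
   where the strict mean comparison must fail — the top module is taken
   with a warning.
5. **Feature sites.** Differential sites are pruned for collinearity
   (variance-ordered greedy, drop when |r| > 0.9 against a kept site),
   then passed to a shadow-feature random-forest selector on the
   stratified 70% training split: each iteration appends permuted
   shadow copies of the sites, and a site scores a hit when its
   impurity importance exceeds the maximum shadow importance; a
   sequential two-sided binomial test against p = 0.5 confirms or
   rejects. A linear SVM on the confirmed sites is evaluated by
   stratified 10-fold cross-validation on the training split and on the
   held-out 30%, with rank-based (Mann–Whitney) AUC.
6. **Key genes.** The intersection of key-module genes with the genes
   of the confirmed sites.
7. **Subgrouping.** Ward clustering (Euclidean, `ward.D2`) of tumor
   samples on key-gene promoter means. When the cluster count is not
   fixed, three internal indices — mean silhouette width,
   Calinski–Harabasz, and Davies–Bouldin (inverted) — each vote for
   their best k in 2..6, the majority wins and ties break toward the
   smaller k. This is a deterministic desk-scale reduction of the
   multi-index consensus idea behind the usual 30-index selectors.

The t-SNE embedding (`embed_2d()`, an exact quadratic implementation
with perplexity calibration, early exaggeration and momentum) is for
display only; no decision consumes its coordinates.

## Shadow-feature selection: why three deviations from the textbook sketch

The common sketch of all-relevant selection — one shadow per surviving
feature, per-iteration binomial tests with Bonferroni over features —
is not null-safe on a fixed sample, and we deviate in three documented
ways:

* **The shadow pool keeps its full size.** Shadows of every *input*
  feature (three independent permutations each, `n_shadows = 3`) are
  appended every iteration, not just shadows of surviving features. If
  the pool shrank as features were rejected, "beating the maximum
  shadow" would become progressively easier, and features that are
  merely chance-correlated with the labels in this sample would be
  confirmed late.
* **The decision level is corrected for sequential looks.** Testing
  after every iteration at a level corrected only for the feature count
  lets a feature whose true hit probability is exactly ½ random-walk
  across the boundary; Bonferroni over features × looks controls the
  family-wise error at the stated α.
* **`mtry` is small (5% of columns).** With many mutually correlated
  relevant sites, impurity importance concentrates on one
  representative per cluster under the default `sqrt(p)`; a small
  `mtry` spreads splits — and therefore importance — across the
  cluster, which is what an *all-relevant* selector wants.

These choices were fixed by pilot simulation during design: with them,
a label-identical feature is confirmed and all of 20 noise features are
rejected in every pilot run, and pure-noise inputs confirm nothing. The
Boruta property simulations use n = 150 samples: at n = 60 the best of
20 "noise" features is typically sample-correlated with the labels at
|r| ≈ 0.3, i.e. genuinely informative *in this sample*, which is not
the behavior the null property is about.

## The synthetic cohort generator

`generate_cohort()` emulates the inputs of a tumor/normal 450K study
with planted structure; the defaults are the package's study
conditions and all tests and the acceptance script run on them.

* **Beta values** are drawn from beta distributions around per-entry
  means (respecting the [0, 1] support). The default concentration 6
  gives a probe-level standard deviation near 0.15 at mid-range means,
  so individual probes are noisy while 3-probe promoter means are
  clean — deliberately the regime arrays live in, and what makes both
  collinearity pruning (probe pairs below |r| = 0.9) and module
  detection (gene pairs far above it) behave as intended on one
  fixture.
* **Key genes** (30, each with 3 promoter probes) are hypomethylated in
  normals (mean 0.15) and hypermethylated in every tumor. The shift is
  `delta_beta` in subgroups where the gene's module carries a "−" and
  `2 * delta_beta` where it carries a "+", so every key probe clears a
  tumor-versus-normal contrast of at least `delta_beta` (default 0.3,
  comfortably past the 0.2 calling threshold) while the single/double
  difference encodes the subgroups. A balanced ± pattern around a
  common center would cancel in the tumor-average contrast and the
  differential step would see nothing — hypermethylation with two
  intensity levels keeps both signals.
* **Modules.** Key genes split into modules; each informative module
  "defines" one subgroup (its "+" subgroup), and the *last* module is
  tumor-wide: shifted equally in all subgroups, hence differential but
  uninformative for subgrouping. Informative modules cohere through
  their shared subgroup pattern plus a mild latent factor (sd 0.05);
  the tumor-wide module has no subgroup variance and gets a stronger
  latent factor (sd 0.12, a methylator-phenotype-like axis) so it is
  still detected — and then scored low, exercising the selection rule
  on a realistic mix instead of a degenerate all-tie. The preset for
  k = 2 ("luminal A") uses 3 modules, the k = 3 preset ("luminal B") 4,
  one informative module per subgroup.
* **Pathways** are drawn over the cohort's gene universe; a designated
  cancer-related subset draws 80% of its genes from the informative
  ("cancer") modules, the rest uniformly. Missingness is injected
  completely at random — the mechanism behind real 450K missingness is
  not characterized, so MCAR is an explicit assumption.
* **Expression.** The ground truth carries a gene × cell-type signature
  (20 markers per type, plus `GZMA`/`PRF1` and the checkpoint genes
  `PDCD1`/`CD274` on the T-cell column) and per-tumor Dirichlet
  proportions whose T-cell fraction decreases from the first subgroup
  to the last, so cytolytic activity is coupled to the planted
  composition. Labeled single cells are gamma draws around signature
  columns; bulk profiles are signature × proportions plus Gaussian
  noise clipped at zero; survival times are exponential with
  per-subgroup hazards and independent exponential censoring calibrated
  to the requested censoring fraction.

What the generator does **not** emulate: probe-type chemistry and
normalization artifacts, batch effects, copy-number contamination of
beta values, spatially correlated missingness, single-cell dropout and
library-size variation, and non-proportional hazards. Passing tests
therefore demonstrate correctness of the algorithms under the stated
statistical structure, not robustness to every artifact of real arrays.

## Deconvolution

`build_signature()` re-derives per-type markers by one-versus-rest
Wilcoxon tests on `log1p` expression (BH-corrected within type,
`log1p` fold change ≥ 1) and sums each type's raw expression over the
marker union. `deconvolve()` standardizes the signature by its global
mean/sd and each bulk profile by its own, fits a linear ν-support
vector regression for ν in {0.25, 0.5, 0.75}, keeps the fit with the
lowest reconstruction RMSE (intercept included), clips negative
coefficients and renormalizes to the simplex. The SVR cost defaults to
10: weak enough shrinkage that the recovered weights are not biased
(the ν tube provides the robustness), while staying in the regime
where the optimizer converges quickly. Under pure Gaussian noise,
clipped least squares is the maximum-likelihood estimator and the SVR
can only match it (the package's tests show agreement to a few 1e-4 in
mean absolute proportion); the SVR's advantage appears under
contamination, where a few blown-up entries derail least squares but
stay outside the ν tube.

Cytolytic activity is the per-sample arithmetic mean of `GZMA` and
`PRF1` expression on the linear scale (a log-scale variant is a flag;
the linear mean is the default because the score is defined directly on
expression values). Methylation specificity replaces a dedicated
differential-region caller with a documented entropy criterion: subgroup
mean betas normalized to a distribution, Shannon entropy in bits, and a
gene is "specific" when its entropy is below the 25% quantile of
candidates *and* its Kruskal–Wallis p is below 0.05 — the same intent
(few-subgroup concentration plus significance) with transparent
arithmetic.

## Numerical conventions and edge cases

* Quartiles use `type = 7` (inclusive linear interpolation) throughout.
* The strict missingness filter keeps a probe missing exactly half the
  samples.
* Zero-variance probes: p = 1 when means agree, p = 0 otherwise.
* Greedy pruning orders by variance, breaking ties by input order;
  correlations against zero-variance features count as 0.
* `boruta_select` canonicalizes features by name order, so its decision
  sets are invariant to the input column order; `max_iter = 0` returns
  everything tentative.
* Cluster labels are size-ranked (`C1` is the largest); `choose_k`
  breaks vote ties toward smaller k; an all-identical input matrix is
  an error, not a cluster.
* The deconvolution simplex is enforced by construction (clip + renorm;
  an all-nonpositive coefficient vector falls back to uniform).
* All generators and every stochastic operation take an explicit seed
  and restore the caller's RNG state.

## Problem sizes

The package's own verification runs at desk scale, chosen so the full
suite and the acceptance script complete comfortably on one CPU: 500
probes × 60 samples per cohort, 30 key genes, 20 pathways; 10 seeds for
module recovery; 100 seeded runs for the selector's reliability (n =
150 samples, 150 trees, 50 iterations); 20 seeds per preset for
end-to-end subgroup recovery, run with a 400-tree forest and 60
selection iterations (the single-fit tests use the full 1000-tree
default); 1000 replicates for the type-I-error checks; 50 mixtures for
deconvolution. The printed cohort sizes of the motivating application
(hundreds of tumors, 450k probes) are orders of magnitude larger; the
algorithms scale but the reference numbers reported there depend on the
private cohorts and are not reproduced here.

## Known limitations

* The static tree cut is deterministic and adequate for block-structured
  fixtures; a dynamic hybrid cut would be the natural extension for
  real arrays with nested module structure.
* The three-index vote for k is a reduction of the usual 30-index
  consensus; on weakly separated cohorts the indices can disagree, and
  the tie-break toward small k is conservative.
* Feature selection decisions are in-sample; at small n, features
  chance-correlated with the labels are genuinely informative in-sample
  and no selector can distinguish them from weak true signal.
* The entropy specificity score approximates, but is not, a
  differential-methylation-region caller.
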