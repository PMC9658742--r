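# The end-to-end fit: from a raw beta matrix with tumor/normal labels to
# key genes and tumor subgroups.

#' Discover methylation-driven subgroups in a tumor cohort
#'
#' Runs the full subgrouping pipeline on a probe x sample beta matrix:
#'
#' 1. restrict to strand-aware promoter probes, drop probes missing in
#'    more than half the samples, impute the rest by probe-level KNN;
#' 2. call differentially methylated sites (tumor vs normal; pooled t
#'    test, BH FDR, `|beta_d| >= 0.2 & fdr < 0.05`) and map them to genes;
#' 3. detect co-methylation modules over the differential genes' promoter
#'    means in tumor samples (weighted correlation network, topological
#'    overlap, average linkage, static cut);
#' 4. score each module by the fraction of its genes inside significantly
#'    enriched pathways and select key modules by the mean/upper-quartile
#'    rule;
#' 5. prune collinear differential sites, select feature sites with the
#'    shadow-feature random-forest procedure on a stratified 7:3 split,
#'    evaluate a linear SVM (10-fold cross-validated and held-out AUC),
#'    and map feature sites to feature genes;
#' 6. intersect key-module genes with feature genes into the key genes;
#' 7. cluster tumor samples on key-gene promoter means (Ward linkage),
#'    choosing the cluster count by three-index vote unless `k` is given.
#'
#' @param beta probe x sample beta matrix, `NA` for missing.
#' @param annotation probe annotation (`probe_id`, `pos`, `strand`,
#'   `gene_symbol`, `tss`).
#' @param pathways a [pathway_collection()].
#' @param groups named sample -> `"tumor"`/`"normal"` vector.
#' @param upstream,downstream promoter window in bp.
#' @param max_missing missingness filter threshold.
#' @param knn_k imputation neighbors.
#' @param min_abs_bd,max_fdr differential flag thresholds.
#' @param soft_power adjacency exponent. The default 6 is the canonical
#'   unsigned-network choice; `NA` picks the power by scale-free fit, which
#'   is only meaningful for gene sets in the hundreds or more.
#' @param min_module_size,cut_height module detection parameters (use a
#'   smaller `min_module_size` for desk-scale cohorts).
#' @param cancer_only restrict pathway-gene pooling to cancer-related
#'   pathway ids when the collection declares them.
#' @param r_max collinearity pruning threshold.
#' @param n_trees,boruta_alpha,boruta_max_iter feature-selection
#'   parameters; the pipeline default of 1000 trees stabilizes impurity
#'   importances across the many mutually correlated candidate sites.
#' @param split_ratio,k_folds classifier evaluation parameters.
#' @param k cluster count; `NULL` chooses it by index vote over `k_range`.
#' @param k_range candidate cluster counts.
#' @param linkage clustering linkage.
#' @param seed integer seed driving every stochastic step.
#' @return An object of class `"methylim"` with components `differential`,
#'   `diff_genes`, `modules`, `enrichment`, `kmscores`, `split`, `boruta`,
#'   `eval`, `feature_genes`, `key_genes`, `choose_k` (when `k` was
#'   chosen), `subgroups`, `gene_means` (tumor sample x key gene matrix),
#'   `params`, `call`.
#' @seealso [predict.methylim()], [plot.methylim()]
#' @examples
#' spec <- cohort_spec(n_probes = 200, n_key_genes = 12, missing_rate = 0,
#'                     seed = 7)
#' cohort <- generate_cohort(spec)
#' pw <- generate_pathways(cohort$truth, n_pathways = 12, seed = 7)
#' fit <- methylim(cohort$beta, cohort$annotation, pw, cohort$groups,
#'                 min_module_size = 4, n_trees = 100, seed = 7)
#' print(fit)
#' @export
methylim <- function(beta, annotation, pathways, groups,
                     upstream = 2000, downstream = 500,
                     max_missing = 0.5, knn_k = 10,
                     min_abs_bd = 0.2, max_fdr = 0.05,
                     soft_power = 6, min_module_size = 30,
                     cut_height = 0.99, cancer_only = FALSE,
                     r_max = 0.9, n_trees = 1000, boruta_alpha = 0.05,
                     boruta_max_iter = 100,
                     split_ratio = 0.7, k_folds = 10,
                     k = NULL, k_range = 2:6, linkage = "ward", seed = 1) {
  cl <- match.call()
  groups <- groups[colnames(beta)]
  if (anyNA(groups) || !all(groups %in% c("tumor", "normal"))) {
    stop("`groups` must label every sample as 'tumor' or 'normal'", call. = FALSE)
  }
  tumor_ids <- names(groups)[groups == "tumor"]
  normal_ids <- names(groups)[groups == "normal"]

  # 1. promoter restriction, QC, imputation
  prom <- promoter_probes(annotation, upstream, downstream)
  beta_p <- beta[intersect(rownames(beta), prom), , drop = FALSE]
  beta_p <- suppressMessages(filter_missingness(beta_p, max_missing))
  beta_p <- knn_impute(beta_p, k = min(knn_k, nrow(beta_p) - 1))

  # 2. differential sites and genes
  differential <- call_differential(beta_p, tumor_ids, normal_ids,
                                    min_abs_bd = min_abs_bd,
                                    max_fdr = max_fdr, ann = annotation)
  diff_genes <- sites_to_genes(differential)
  if (length(diff_genes) < 4) {
    stop("fewer than 4 differential genes; nothing to subgroup", call. = FALSE)
  }

  # 3. co-methylation modules on tumor promoter means
  gm_tumor <- promoter_gene_means(beta_p, annotation, genes = diff_genes,
                                  upstream = upstream, downstream = downstream)
  gm_tumor <- gm_tumor[, tumor_ids, drop = FALSE]
  if (is.na(soft_power)) {
    soft_power <- as.numeric(pick_soft_threshold(gm_tumor))
  }
  modules <- detect_modules(gm_tumor, soft_power,
                            min_module_size = min_module_size,
                            cut_height = cut_height)

  # 4. pathway enrichment and key-module selection
  enrichment <- enrich_pathways(intersect(diff_genes, pathways$universe),
                                pathways)
  kmscores <- select_key_modules(
    compute_kmscores(modules, enrichment, pathways, cancer_only = cancer_only)
  )

  # 5. feature sites -> feature genes
  diff_probes <- differential$probe_id[differential$is_differential]
  split <- make_split(groups, ratio = split_ratio, seed = seed)
  x_sites <- t(beta_p[diff_probes, , drop = FALSE])
  kept_sites <- prune_collinear(t(x_sites[split$train_ids, , drop = FALSE]),
                                r_max = r_max)
  boruta <- boruta_select(x_sites[split$train_ids, kept_sites, drop = FALSE],
                          groups[split$train_ids], n_trees = n_trees,
                          alpha = boruta_alpha, max_iter = boruta_max_iter,
                          seed = seed)
  feature_sites <- boruta$confirmed
  if (length(feature_sites) == 0) {
    stop("no feature sites confirmed; cohort carries no detectable signal",
         call. = FALSE)
  }
  eval <- train_eval(x_sites, groups, feature_sites, split,
                     k_folds = k_folds, seed = seed)
  feature_genes <- sort(unique(
    annotation$gene_symbol[match(feature_sites, annotation$probe_id)]))

  # 6. key genes
  key <- intersect_key_genes(kmscores, feature_genes)
  if (length(key$genes) < 2) {
    stop("fewer than 2 key genes; subgrouping is impossible", call. = FALSE)
  }

  # 7. subgroup tumor samples on key-gene promoter means
  gm_key <- t(promoter_gene_means(beta_p, annotation, genes = key$genes,
                                  upstream = upstream,
                                  downstream = downstream)[, tumor_ids,
                                                           drop = FALSE])
  kinfo <- NULL
  if (is.null(k)) {
    kinfo <- choose_k(gm_key, k_range = k_range, linkage = linkage)
    k <- kinfo$k
  }
  subgroups <- cluster_samples(gm_key, k, linkage = linkage)

  structure(
    list(differential = differential, diff_genes = diff_genes,
         modules = modules, enrichment = enrichment, kmscores = kmscores,
         split = split, boruta = boruta, eval = eval,
         feature_genes = feature_genes, key_genes = key,
         choose_k = kinfo, subgroups = subgroups, gene_means = gm_key,
         groups = groups,
         params = list(upstream = upstream, downstream = downstream,
                       soft_power = soft_power,
                       min_module_size = min_module_size,
                       linkage = linkage, seed = seed),
         call = cl),
    class = "methylim"
  )
}

#' @export
print.methylim <- function(x, ...) {
  cat("Methylation-driven subgroup discovery\n")
  cat(sprintf("  %d tumor / %d normal samples\n",
              sum(x$groups == "tumor"), sum(x$groups == "normal")))
  cat(sprintf("  differential sites: %d of %d tested; differential genes: %d\n",
              sum(x$differential$is_differential), nrow(x$differential),
              length(x$diff_genes)))
  cat(sprintf("  modules: %d (soft power %g); key modules: %s\n",
              length(x$modules$module_sizes), x$params$soft_power,
              paste(names(x$kmscores$selected)[x$kmscores$selected],
                    collapse = ", ")))
  cat(sprintf("  feature sites confirmed: %d -> feature genes: %d\n",
              length(x$boruta$confirmed), length(x$feature_genes)))
  cat(sprintf("  key genes: %d\n", length(x$key_genes$genes)))
  cat(sprintf("  subgroups: k = %d (%s)\n", x$subgroups$k,
              paste(sprintf("%s: %d", names(x$subgroups$sizes),
                            x$subgroups$sizes), collapse = ", ")))
  invisible(x)
}

#' @export
summary.methylim <- function(object, ...) {
  structure(
    list(fit = object,
         auc = c(train = object$eval$auc_train, cv = object$eval$auc_cv,
                 heldout = object$eval$auc_heldout),
         kmscores = object$kmscores$scores,
         key_genes = object$key_genes$genes,
         sizes = object$subgroups$sizes),
    class = "summary.methylim"
  )
}

#' @export
print.summary.methylim <- function(x, ...) {
  print(x$fit)
  cat("\nClassifier AUC:\n"); print(round(x$auc, 3))
  cat("\nModule scores:\n"); print(round(x$kmscores, 3))
  cat("\nKey genes:\n"); print(x$key_genes)
  invisible(x)
}

#' Assign new samples to discovered subgroups
#'
#' New samples are mapped onto the fitted subgroups by nearest subgroup
#' centroid in key-gene promoter-mean space (Euclidean distance), after
#' the same promoter restriction and imputation as in the fit.
#'
#' @param object a fitted `"methylim"`.
#' @param beta probe x sample beta matrix for the new samples.
#' @param annotation probe annotation matching `beta`.
#' @param ... unused.
#' @return Named character vector of subgroup labels.
#' @export
predict.methylim <- function(object, beta, annotation, ...) {
  beta <- suppressMessages(filter_missingness(beta))
  if (anyNA(beta)) beta <- knn_impute(beta, k = min(10, nrow(beta) - 1))
  gm <- t(promoter_gene_means(beta, annotation,
                              genes = object$key_genes$genes,
                              upstream = object$params$upstream,
                              downstream = object$params$downstream))
  common <- intersect(colnames(gm), colnames(object$gene_means))
  if (length(common) < 2) stop("too few key genes measured in the new samples", call. = FALSE)
  sub <- object$subgroups$subgroup
  cent <- do.call(rbind, lapply(sort(unique(sub)), function(l) {
    colMeans(object$gene_means[names(sub)[sub == l], common, drop = FALSE])
  }))
  rownames(cent) <- sort(unique(sub))
  d <- as.matrix(dist(rbind(gm[, common, drop = FALSE], cent)))
  d <- d[seq_len(nrow(gm)), nrow(gm) + seq_len(nrow(cent)), drop = FALSE]
  stats::setNames(rownames(cent)[apply(d, 1, which.min)], rownames(gm))
}

#' Plot a fitted subgrouping as a 2-D embedding
#'
#' Embeds the tumor samples' key-gene promoter means with [embed_2d()]
#' and colors them by subgroup.
#'
#' @param x a fitted `"methylim"`.
#' @param seed embedding seed.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the coordinate matrix.
#' @export
plot.methylim <- function(x, seed = 1, ...) {
  coords <- embed_2d(x$gene_means, seed = seed)
  sub <- x$subgroups$subgroup[rownames(coords)]
  labs <- sort(unique(sub))
  cols <- rainbow(length(labs))
  plot(coords, col = cols[match(sub, labs)], pch = 19,
       xlab = "dimension 1", ylab = "dimension 2", ...)
  legend("topright", legend = labs, col = cols, pch = 19, bty = "n")
  invisible(coords)
}
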