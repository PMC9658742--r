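# Hypergeometric pathway enrichment, key-module scoring (the fraction of a
# module's genes that fall inside significantly enriched pathways), key
# module selection by the mean / upper-quartile rule, and the final key-gene
# intersection.

#' Hypergeometric pathway enrichment
#'
#' One-sided upper-tail hypergeometric test per pathway: the probability
#' of drawing at least the observed overlap when `|query|` genes are
#' drawn from the universe without replacement. Raw p values are
#' thresholded at `alpha` without multiplicity correction (downstream
#' scoring uses the raw p < 0.05 rule).
#'
#' @param query character vector of genes of interest; genes outside the
#'   universe are dropped with a warning.
#' @param pc a [pathway_collection()].
#' @param alpha significance threshold on the raw p value.
#' @return A `data.frame`: `pathway_id`, `pathway_size`, `overlap_count`,
#'   `p_value`, `significant`, sorted by p value.
#' @export
enrich_pathways <- function(query, pc, alpha = 0.05) {
  stopifnot(inherits(pc, "pathway_collection"))
  if (length(pc$universe) == 0) stop("empty gene universe", call. = FALSE)
  query <- unique(query)
  stray <- setdiff(query, pc$universe)
  if (length(stray) > 0) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(stray)))
    query <- intersect(query, pc$universe)
  }
  n_univ <- length(pc$universe)
  n_query <- length(query)
  rows <- lapply(names(pc$pathways), function(id) {
    pw <- unique(pc$pathways[[id]])
    ov <- length(intersect(pw, query))
    p <- phyper(ov - 1, length(pw), n_univ - length(pw), n_query,
                lower.tail = FALSE)
    data.frame(pathway_id = id, pathway_size = length(pw), overlap_count = ov,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway_id = character(0), pathway_size = integer(0),
                      overlap_count = integer(0), p_value = numeric(0))
  }
  out$significant <- out$p_value < alpha
  out[order(out$p_value, out$pathway_id), , drop = FALSE]
}

#' Score modules against enriched-pathway genes
#'
#' Let `KPGenes` be the union of the genes of all significant pathways
#' (optionally restricted to the collection's cancer-related pathway ids).
#' The score of module `i` with gene set `Gene_i` is
#' `|KPGenes intersect Gene_i| / |Gene_i|`, a fraction in \[0, 1\]. Grey
#' (unassigned) genes are excluded from scoring.
#'
#' @param modules a `"module_partition"` with at least one non-grey module.
#' @param enr enrichment results from [enrich_pathways()].
#' @param pc the [pathway_collection()] the enrichment was run against.
#' @param cancer_only restrict `KPGenes` to significant pathways among
#'   `pc$cancer_related_ids` (default uses all significant pathways).
#' @return A list of class `"kmscore_table"`: `scores` (named numeric),
#'   `selected` (logical, filled by [select_key_modules()]), `kp_genes`,
#'   `module_genes` (named list) and `key_module_genes`.
#' @export
compute_kmscores <- function(modules, enr, pc, cancer_only = FALSE) {
  stopifnot(inherits(modules, "module_partition"))
  gene_sets <- module_gene_sets(modules)
  if (length(gene_sets) == 0) stop("no non-grey modules to score", call. = FALSE)
  if (any(lengths(gene_sets) == 0)) stop("module with zero genes", call. = FALSE)
  sig_ids <- enr$pathway_id[enr$significant]
  if (isTRUE(cancer_only) && !is.null(pc$cancer_related_ids)) {
    sig_ids <- intersect(sig_ids, pc$cancer_related_ids)
  }
  kp_genes <- sort(unique(unlist(pc$pathways[sig_ids])))
  scores <- vapply(gene_sets, function(g) {
    length(intersect(kp_genes, g)) / length(g)
  }, numeric(1))
  structure(
    list(scores = scores,
         selected = stats::setNames(rep(NA, length(scores)), names(scores)),
         kp_genes = kp_genes, module_genes = gene_sets,
         key_module_genes = character(0)),
    class = "kmscore_table"
  )
}

#' Select key modules by the mean / upper-quartile rule
#'
#' A module is selected when its score is strictly greater than the mean
#' score and at least the upper quartile of the scores. The upper
#' quartile uses the inclusive linear-interpolation convention
#' (`quantile(..., type = 7)`); on scores `{0.5, 0.2, 0.8}` the mean is
#' 0.5, Q3 is 0.65 and only the 0.8 module passes. If no module passes
#' both tests (for instance when all scores are equal, where the strict
#' mean comparison fails), the top-scoring module is selected with a
#' warning. The union of selected modules' genes becomes the key-module
#' gene set.
#'
#' @param t a `"kmscore_table"` from [compute_kmscores()].
#' @return The table with `selected` and `key_module_genes` filled in.
#' @export
select_key_modules <- function(t) {
  stopifnot(inherits(t, "kmscore_table"))
  s <- t$scores
  if (length(s) == 0) stop("no scored modules", call. = FALSE)
  q3 <- unname(quantile(s, 0.75, type = 7))
  sel <- s > mean(s) & s >= q3
  if (!any(sel)) {
    warning("no module passed the mean/upper-quartile rule; selecting the top score")
    # ties broken by module name for determinism
    top <- names(s)[order(-s, names(s))][1]
    sel[] <- FALSE
    sel[top] <- TRUE
  }
  t$selected <- sel
  t$key_module_genes <- sort(unique(unlist(t$module_genes[sel])))
  t
}

#' @export
print.kmscore_table <- function(x, ...) {
  cat("Module scores (fraction of genes in enriched pathways):\n")
  df <- data.frame(module = names(x$scores), score = round(unname(x$scores), 4),
                   selected = unname(x$selected))
  print(df, row.names = FALSE)
  if (length(x$key_module_genes) > 0) {
    cat(sprintf("Key-module genes: %d\n", length(x$key_module_genes)))
  }
  invisible(x)
}

#' Intersect key-module genes with classifier feature genes
#'
#' The key genes driving subgrouping are the intersection of the selected
#' modules' genes and the genes of the classifier-selected feature sites.
#' An empty intersection is allowed but warned about, since downstream
#' clustering is then impossible.
#'
#' @param t a `"kmscore_table"` after [select_key_modules()].
#' @param feature_genes character vector of classifier feature genes.
#' @return A list of class `"key_gene_set"`: `genes` and `provenance`
#'   (data frame gene -> module).
#' @export
intersect_key_genes <- function(t, feature_genes) {
  stopifnot(inherits(t, "kmscore_table"))
  if (length(t$key_module_genes) == 0 || length(feature_genes) == 0) {
    stop("both key-module genes and feature genes must be nonempty", call. = FALSE)
  }
  genes <- sort(intersect(t$key_module_genes, unique(feature_genes)))
  if (length(genes) == 0) {
    warning("key-module genes and feature genes do not intersect; ",
            "no key genes available for subgrouping")
  }
  module_of <- rep(names(t$module_genes), lengths(t$module_genes))
  names(module_of) <- unlist(t$module_genes)
  structure(
    list(genes = genes,
         provenance = data.frame(gene = genes,
                                 module = unname(module_of[genes]),
                                 stringsAsFactors = FALSE)),
    class = "key_gene_set"
  )
}
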