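# Promoter mapping, probe QC, KNN imputation and differential methylation
# calling on array beta values.

#' Probes falling in strand-aware promoter windows
#'
#' The promoter is taken as the window from `upstream` bp upstream to
#' `downstream` bp downstream of the transcription start, oriented along
#' the direction of transcription. Coordinates are 0-based; the window is
#' half-open on the downstream side. For a `+` strand gene a probe at
#' position `pos` is included when `tss - upstream <= pos < tss +
#' downstream`; for a `-` strand gene the window is reflected
#' (`tss - downstream < pos <= tss + upstream`). A probe exactly at the
#' TSS is included on either strand.
#'
#' @param ann probe annotation (`probe_id`, `pos`, `strand`, `tss`).
#' @param upstream,downstream window widths in bp.
#' @return Character vector of probe ids inside their gene's promoter.
#' @export
promoter_probes <- function(ann, upstream = 2000, downstream = 500) {
  bad <- !ann$strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand for probe(s): ",
         paste(head(ann$probe_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  plus <- ann$strand == "+"
  keep <- ifelse(plus,
                 ann$pos >= ann$tss - upstream & ann$pos < ann$tss + downstream,
                 ann$pos > ann$tss - downstream & ann$pos <= ann$tss + upstream)
  ann$probe_id[keep]
}

#' Drop probes with excessive missingness
#'
#' Removes probes whose fraction of missing beta values strictly exceeds
#' `max_missing` ("exceeding" is strict: a probe missing exactly half of
#' the samples is kept at the default). The sample set is unchanged.
#'
#' @param beta probe x sample matrix, `NA` for missing.
#' @param max_missing maximum tolerated missing fraction.
#' @return The filtered matrix; the number of dropped probes is reported
#'   via `message()` and attached as attribute `"n_dropped"`.
#' @export
filter_missingness <- function(beta, max_missing = 0.5) {
  frac <- rowMeans(is.na(beta))
  keep <- frac <= max_missing
  if (!any(keep)) stop("all probes exceed the missingness threshold", call. = FALSE)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("filter_missingness: dropped %d of %d probes", n_dropped,
                    nrow(beta)))
  }
  out <- beta[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' K-nearest-neighbor imputation over probe rows
#'
#' Each missing entry is replaced by the mean beta of the `k` nearest
#' probes (root-mean-square Euclidean distance over the samples both
#' probes observe; ties broken by probe order) that observe the sample in
#' question. A probe with no overlapping observations with any neighbor
#' falls back to the sample (column) mean. Imputing an already-complete
#' matrix is the identity.
#'
#' @param beta probe x sample matrix with `NA` for missing; every probe
#'   must retain at least one observed value.
#' @param k number of neighbor probes (must be < number of probes).
#' @return A complete matrix with all values in \[0, 1\].
#' @export
knn_impute <- function(beta, k = 10) {
  if (k >= nrow(beta)) stop("`k` must be smaller than the number of probes", call. = FALSE)
  if (any(rowSums(!is.na(beta)) == 0)) {
    stop("every probe must have at least one observed value", call. = FALSE)
  }
  miss_rows <- which(rowSums(is.na(beta)) > 0)
  if (length(miss_rows) == 0) return(beta)
  out <- beta
  obs <- !is.na(beta)
  col_means <- colMeans(beta, na.rm = TRUE)
  for (i in miss_rows) {
    xi <- beta[i, ]
    # RMS distance over commonly observed samples, Inf when no overlap
    shared <- obs & rep(obs[i, ], each = nrow(beta))
    diff2 <- sweep(beta, 2, xi)^2
    diff2[!shared] <- NA
    n_shared <- rowSums(shared)
    d <- sqrt(rowSums(diff2, na.rm = TRUE) / pmax(n_shared, 1))
    d[n_shared == 0] <- Inf
    d[i] <- Inf
    ord <- order(d, seq_along(d))  # ties broken by probe order
    for (j in which(is.na(xi))) {
      nb <- ord[obs[ord, j] & is.finite(d[ord])]
      nb <- nb[seq_len(min(k, length(nb)))]
      out[i, j] <- if (length(nb) > 0) mean(beta[nb, j]) else col_means[j]
    }
  }
  out
}

#' Differential methylation calling
#'
#' Per-probe two-sample t test of case versus control beta values (pooled
#' variance by default, Welch with `var_equal = FALSE`), Benjamini-Hochberg
#' FDR across all tested probes, and the dual flag
#' `|beta_d| >= min_abs_bd & fdr < max_fdr`, where `beta_d` is the
#' case-mean minus control-mean beta difference. Probes with zero pooled
#' variance get p = 1 when the group means agree (keeps the FDR step
#' well-defined) and p = 0 when they differ.
#'
#' @param beta complete probe x sample matrix (impute first).
#' @param case_ids,control_ids disjoint sample id vectors, each of size
#'   at least 2.
#' @param min_abs_bd,max_fdr flag thresholds.
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @param ann optional annotation to carry `gene_symbol` into the result.
#' @return A `data.frame`: `probe_id`, `gene_symbol` (if annotated),
#'   `mean_case`, `mean_control`, `beta_d`, `p_value`, `fdr`,
#'   `is_differential`.
#' @export
call_differential <- function(beta, case_ids, control_ids, min_abs_bd = 0.2,
                              max_fdr = 0.05, var_equal = TRUE, ann = NULL) {
  if (length(intersect(case_ids, control_ids)) > 0) {
    stop("case and control sample sets overlap", call. = FALSE)
  }
  if (length(case_ids) < 2 || length(control_ids) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  missing <- setdiff(c(case_ids, control_ids), colnames(beta))
  if (length(missing) > 0) {
    stop("samples absent from the matrix: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- beta[, case_ids, drop = FALSE]
  y <- beta[, control_ids, drop = FALSE]
  if (anyNA(x) || anyNA(y)) stop("matrix contains missing values; impute first", call. = FALSE)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)
  bd <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- ifelse(se > 0, 2 * pt(-abs(bd / se), df = df),
              ifelse(bd == 0, 1, 0))
  fdr <- p.adjust(p, method = "BH")
  out <- data.frame(
    probe_id = rownames(beta),
    mean_case = m1, mean_control = m2, beta_d = bd,
    p_value = p, fdr = fdr,
    is_differential = abs(bd) >= min_abs_bd & fdr < max_fdr,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(ann)) {
    out$gene_symbol <- ann$gene_symbol[match(out$probe_id, ann$probe_id)]
    out <- out[, c("probe_id", "gene_symbol", "mean_case", "mean_control",
                   "beta_d", "p_value", "fdr", "is_differential")]
  }
  out
}

#' Map flagged probes to differential genes
#'
#' A gene is differentially methylated when at least one of its (promoter)
#' probes is flagged.
#'
#' @param dt a differential table from [call_differential()]; must carry
#'   `gene_symbol` (pass `ann` there, or supply `ann` here).
#' @param ann optional annotation used when `dt` lacks `gene_symbol`.
#' @return Sorted character vector of unique differential gene symbols.
#' @export
sites_to_genes <- function(dt, ann = NULL) {
  if (is.null(dt$gene_symbol)) {
    if (is.null(ann)) stop("differential table lacks gene symbols; supply `ann`", call. = FALSE)
    dt$gene_symbol <- ann$gene_symbol[match(dt$probe_id, ann$probe_id)]
  }
  sort(unique(dt$gene_symbol[dt$is_differential & !is.na(dt$gene_symbol)]))
}

#' Gene-level promoter methylation means
#'
#' Averages beta values over each gene's promoter probes, yielding the
#' gene x sample matrix the module detector and the subgroup clustering
#' operate on.
#'
#' @param beta complete probe x sample matrix.
#' @param ann probe annotation.
#' @param genes optional gene subset.
#' @param upstream,downstream promoter window (see [promoter_probes()]).
#' @return Gene x sample numeric matrix.
#' @export
promoter_gene_means <- function(beta, ann, genes = NULL, upstream = 2000,
                                downstream = 500) {
  prom <- promoter_probes(ann, upstream, downstream)
  ann <- ann[ann$probe_id %in% prom & ann$probe_id %in% rownames(beta), ]
  if (!is.null(genes)) ann <- ann[ann$gene_symbol %in% genes, ]
  if (nrow(ann) == 0) stop("no promoter probes for the requested genes", call. = FALSE)
  sub <- beta[ann$probe_id, , drop = FALSE]
  rs <- rowsum(sub, group = ann$gene_symbol)
  counts <- as.vector(table(ann$gene_symbol)[rownames(rs)])
  rs / counts
}
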