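# Cell-type signature construction from labeled single cells, nu-SVR
# deconvolution of bulk expression, cytolytic activity, and an
# entropy-based methylation specificity score.

#' Build a cell-type signature matrix from labeled single cells
#'
#' Per cell type, a one-versus-rest Wilcoxon rank-sum test on `log1p`
#' expression (Benjamini-Hochberg corrected within the type) defines
#' marker genes as those with `fdr < max_p` and a `log1p`-scale fold
#' change of at least `min_lfc` in favor of the type. The signature
#' column of a type is the sum of its cells' raw expression, restricted
#' to the union of all marker genes. A type with no markers is an error
#' (it cannot be distinguished in deconvolution).
#'
#' @param expr gene x cell expression matrix.
#' @param labels named vector cell -> type (at least 2 cells per type).
#' @param min_lfc minimum `log1p`-scale mean difference.
#' @param max_p marker FDR threshold.
#' @return A list of class `"signature_matrix"`: `signature` (marker gene
#'   x type matrix), `markers` (named list type -> genes), `cell_types`.
#' @export
build_signature <- function(expr, labels, min_lfc = 1.0, max_p = 0.05) {
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) stop("every cell must be labeled", call. = FALSE)
  types <- sort(unique(labels))
  if (length(types) < 2) stop("need at least 2 cell types", call. = FALSE)
  if (any(table(labels) < 2)) stop("need at least 2 cells per type", call. = FALSE)
  lx <- log1p(expr)
  markers <- lapply(types, function(t) {
    in_t <- labels == t
    lfc <- rowMeans(lx[, in_t, drop = FALSE]) - rowMeans(lx[, !in_t, drop = FALSE])
    p <- apply(lx, 1, function(g) {
      if (all(g[in_t] == g[!in_t][1]) && all(g == g[1])) return(1)
      suppressWarnings(wilcox.test(g[in_t], g[!in_t])$p.value)
    })
    p[is.na(p)] <- 1
    fdr <- p.adjust(p, method = "BH")
    rownames(expr)[fdr < max_p & lfc >= min_lfc]
  })
  names(markers) <- types
  empty <- types[lengths(markers) == 0]
  if (length(empty) > 0) {
    stop("no marker genes found for cell type(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  marker_union <- sort(unique(unlist(markers)))
  sig <- vapply(types, function(t) {
    rowSums(expr[marker_union, labels == t, drop = FALSE])
  }, numeric(length(marker_union)))
  rownames(sig) <- marker_union
  structure(list(signature = sig, markers = markers, cell_types = types),
            class = "signature_matrix")
}

# nu-SVR fit of one standardized bulk profile on the standardized
# signature; returns simplex proportions plus fit quality.
svr_deconvolve_one <- function(ys, xs, nu_grid, cost) {
  best <- NULL
  for (nu in nu_grid) {
    fit <- e1071::svm(xs, ys, type = "nu-regression", kernel = "linear",
                      nu = nu, cost = cost, scale = FALSE)
    w_raw <- drop(crossprod(fit$coefs, fit$SV))
    pred <- drop(xs %*% w_raw) - fit$rho
    rmse <- sqrt(mean((ys - pred)^2))
    w <- w_raw
    w[w < 0] <- 0
    if (sum(w) == 0) w[] <- 1 / length(w)
    if (is.null(best) || rmse < best$rmse) {
      best <- list(w = w / sum(w), rmse = rmse,
                   r = suppressWarnings(cor(ys, pred)), nu = nu)
    }
  }
  best
}

#' Deconvolve bulk expression into cell-type proportions
#'
#' Support-vector deconvolution in the style of signature-based
#' immune-infiltration estimators: genes are intersected with the
#' signature by name, both the signature matrix and each bulk profile are
#' standardized (the signature by its global mean/sd, each profile by its
#' own), and a linear nu-support-vector regression of the profile on the
#' signature columns is fit for each value in `nu_grid`. The fit with the
#' lowest reconstruction RMSE wins; its coefficients are clipped at zero
#' and renormalized onto the simplex.
#'
#' @param bulk gene x sample expression matrix.
#' @param sig a `"signature_matrix"` (or a plain gene x type matrix).
#' @param nu_grid candidate nu values.
#' @param cost SVR cost parameter. The default keeps shrinkage weak — the
#'   nu tube already provides robustness, and strong ridge-style
#'   shrinkage would distort the recovered simplex weights — while
#'   remaining in the regime where the optimizer converges quickly.
#' @return A list of class `"proportion_matrix"`: `proportions` (sample x
#'   type, rows on the simplex), `fit_quality` (per-sample RMSE,
#'   correlation and chosen nu).
#' @export
deconvolve <- function(bulk, sig, nu_grid = c(0.25, 0.5, 0.75), cost = 10) {
  if (inherits(sig, "signature_matrix")) sig <- sig$signature
  common <- intersect(rownames(bulk), rownames(sig))
  if (length(common) == 0) stop("bulk and signature share no genes", call. = FALSE)
  if (length(common) < ncol(sig)) {
    stop("need at least as many shared genes as cell types", call. = FALSE)
  }
  x <- sig[common, , drop = FALSE]
  xs <- (x - mean(x)) / sd(as.vector(x))
  n <- ncol(bulk)
  props <- matrix(0, nrow = n, ncol = ncol(sig),
                  dimnames = list(colnames(bulk), colnames(sig)))
  fq <- data.frame(sample_id = colnames(bulk), rmse = NA_real_, r = NA_real_,
                   nu = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    yj <- bulk[common, j]
    ys <- (yj - mean(yj)) / sd(yj)
    best <- svr_deconvolve_one(ys, xs, nu_grid, cost)
    props[j, ] <- best$w
    fq$rmse[j] <- best$rmse
    fq$r[j] <- best$r
    fq$nu[j] <- best$nu
  }
  structure(list(proportions = props, fit_quality = fq),
            class = "proportion_matrix")
}

#' Cytolytic activity score
#'
#' The per-sample arithmetic mean of the expression of the cytolytic
#' effector genes (granzyme A and perforin by default). Linear scale; set
#' `log_scale = TRUE` for the mean of `log1p` expression.
#'
#' @param bulk gene x sample expression matrix.
#' @param gzma,prf1 gene symbols of the two effectors.
#' @param log_scale average on the `log1p` scale instead.
#' @return Named per-sample numeric vector.
#' @export
compute_cyt <- function(bulk, gzma = "GZMA", prf1 = "PRF1", log_scale = FALSE) {
  missing <- setdiff(c(gzma, prf1), rownames(bulk))
  if (length(missing) > 0) {
    stop("gene(s) absent from the matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- bulk[c(gzma, prf1), , drop = FALSE]
  if (log_scale) m <- log1p(m)
  colMeans(m)
}

#' Entropy-based subgroup methylation specificity
#'
#' Scores how concentrated a gene's methylation is in one subgroup: the
#' subgroup mean betas are normalized to a distribution `p_s` and scored
#' by Shannon entropy `H = -sum p_s log2 p_s` (low entropy = specific to
#' few subgroups). A gene is flagged "specific" when its entropy falls
#' below the `entropy_quantile` of all candidate genes and its
#' Kruskal-Wallis p value across subgroups is below `max_p`. An all-zero
#' gene is assigned the maximal entropy `log2(k)` and never flagged.
#'
#' @param subgroup_means gene x subgroup matrix of mean beta values.
#' @param kw_p named per-gene Kruskal-Wallis p values.
#' @param entropy_quantile flagging quantile of the entropy distribution.
#' @param max_p Kruskal-Wallis threshold.
#' @return A `data.frame`: `gene`, `entropy` (bits), `kw_p`, `specific`.
#' @export
methylation_specificity <- function(subgroup_means, kw_p,
                                    entropy_quantile = 0.25, max_p = 0.05) {
  if (ncol(subgroup_means) < 2) stop("need at least 2 subgroups", call. = FALSE)
  if (any(subgroup_means < 0 | subgroup_means > 1, na.rm = TRUE)) {
    stop("subgroup means must lie in [0, 1]", call. = FALSE)
  }
  k <- ncol(subgroup_means)
  h <- apply(subgroup_means, 1, function(m) {
    s <- sum(m)
    if (s == 0) return(log2(k))
    p <- m / s
    -sum(ifelse(p > 0, p * log2(p), 0))
  })
  kw_p <- kw_p[rownames(subgroup_means)]
  cutoff <- quantile(h, entropy_quantile, type = 7)
  all_zero <- rowSums(subgroup_means) == 0
  specific <- h < cutoff & !is.na(kw_p) & kw_p < max_p & !all_zero
  data.frame(gene = rownames(subgroup_means), entropy = unname(h),
             kw_p = unname(kw_p), specific = unname(specific),
             row.names = NULL, stringsAsFactors = FALSE)
}
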