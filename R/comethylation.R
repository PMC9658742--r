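# Weighted co-methylation network: soft threshold selection, topological
# overlap, and module detection by average-linkage clustering with a
# static tree cut.

# WGCNA's conventional module color order, used to name modules by size rank.
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white"
)

#' Pick the soft-thresholding power for a weighted correlation network
#'
#' For each candidate power `b` the unsigned adjacency is
#' `|cor(g_i, g_j)|^b`. The connectivity distribution is binned on the
#' log scale and the scale-free fit R^2 is the squared correlation of
#' log-frequency with log-connectivity, signed negatively when the slope
#' is positive (a scale-free topology requires a decreasing tail). The
#' smallest power reaching `r2_target` is returned; if none does, the
#' power with the best signed R^2.
#'
#' @param x gene x sample matrix of methylation levels.
#' @param powers candidate powers.
#' @param r2_target scale-free fit target.
#' @param n_bins connectivity histogram bins (at least 5 used).
#' @return The chosen power, with the per-power fit table attached as
#'   attribute `"fit_table"`.
#' @export
pick_soft_threshold <- function(x, powers = 1:20, r2_target = 0.85,
                                n_bins = 10) {
  if (nrow(x) < 10 || ncol(x) < 3) {
    stop("need at least 10 genes and 3 samples", call. = FALSE)
  }
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    stop("constant gene rows: ",
         paste(head(rownames(x)[sds == 0], 5), collapse = ", "), call. = FALSE)
  }
  n_bins <- max(n_bins, 5)
  ac <- abs(cor(t(x)))
  diag(ac) <- 0
  fit <- vapply(powers, function(b) {
    k <- rowSums(ac^b)
    k <- k[k > 0]
    if (length(unique(k)) < 2) return(NA_real_)
    cuts <- cut(k, breaks = n_bins)
    freq <- tapply(k, cuts, length)
    kmid <- tapply(k, cuts, mean)
    ok <- !is.na(freq) & freq > 0
    if (sum(ok) < 2) return(NA_real_)
    lx <- log10(kmid[ok]); ly <- log10(freq[ok])
    f <- lm(ly ~ lx)
    unname(-sign(coef(f)[2]) * summary(f)$r.squared)
  }, numeric(1))
  reach <- which(!is.na(fit) & fit >= r2_target)
  power <- if (length(reach) > 0) powers[min(reach)] else powers[which.max(fit)]
  structure(power, fit_table = data.frame(power = powers, signed_r2 = fit))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`, where `k` is the connectivity (row sum) of the adjacency
#' with a zero diagonal. Entries lie in \[0, 1\] for adjacencies in
#' \[0, 1\].
#'
#' @param adjacency symmetric nonnegative matrix (diagonal ignored).
#' @return The TOM, symmetric with unit diagonal.
#' @export
compute_tom <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-methylation modules
#'
#' Builds the unsigned adjacency `|cor|^soft_power` over genes, converts
#' it to the topological overlap dissimilarity `1 - TOM`, clusters with
#' average linkage, and applies a static cut at
#' `cut_height * max(tree height)`. Clusters smaller than
#' `min_module_size` are relabeled `"grey"` (unassigned); the remaining
#' modules are named by decreasing size using the conventional module
#' color order (turquoise, blue, brown, ...).
#'
#' @param x gene x sample methylation matrix.
#' @param soft_power adjacency exponent (>= 1), e.g. from
#'   [pick_soft_threshold()].
#' @param min_module_size smallest retained module.
#' @param cut_height static cut as a fraction of the maximum merge height.
#' @return A list of class `"module_partition"`: `module` (named character
#'   vector gene -> color), `module_sizes`, `soft_power`, `cut_height`.
#' @export
detect_modules <- function(x, soft_power, min_module_size = 30,
                           cut_height = 0.99) {
  if (soft_power < 1) stop("`soft_power` must be >= 1", call. = FALSE)
  genes <- rownames(x) %||% paste0("g", seq_len(nrow(x)))
  if (nrow(x) < min_module_size) {
    warning("fewer genes than `min_module_size`; everything is grey")
    part <- stats::setNames(rep("grey", nrow(x)), genes)
    return(structure(list(module = part, module_sizes = integer(0),
                          soft_power = soft_power, cut_height = cut_height),
                     class = "module_partition"))
  }
  ac <- abs(cor(t(x)))^soft_power
  diag(ac) <- 0
  tom <- compute_tom(ac)
  d <- as.dist(1 - tom)
  tree <- hclust(d, method = "average")
  cl <- cutree(tree, h = cut_height * max(tree$height))
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(cl))
  if (length(keep) > 0) {
    ranked <- keep[order(-sizes[keep], as.integer(keep))]
    colors <- module_colors[seq_along(ranked)]
    for (i in seq_along(ranked)) {
      labels[cl == as.integer(ranked[i])] <- colors[i]
    }
  }
  part <- stats::setNames(labels, genes)
  non_grey <- part[part != "grey"]
  structure(
    list(module = part,
         module_sizes = sort(table(non_grey), decreasing = TRUE),
         soft_power = as.numeric(soft_power), cut_height = cut_height),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  n <- length(x$module)
  n_grey <- sum(x$module == "grey")
  cat(sprintf("Co-methylation modules: %d genes, %d modules, %d unassigned (grey)\n",
              n, length(x$module_sizes), n_grey))
  if (length(x$module_sizes) > 0) {
    print(x$module_sizes)
  }
  invisible(x)
}

#' Genes of each non-grey module
#'
#' @param part a `"module_partition"`.
#' @return Named list module color -> gene vector (grey excluded).
#' @export
module_gene_sets <- function(part) {
  stopifnot(inherits(part, "module_partition"))
  mods <- setdiff(unique(part$module), "grey")
  stats::setNames(lapply(mods, function(m) names(part$module)[part$module == m]),
                  mods)
}
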