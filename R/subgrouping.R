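# Sample subgrouping: hierarchical clustering on key-gene promoter
# methylation, a consensus choice of the cluster count, and a 2-D
# stochastic neighbor embedding for display.

# Internal validity indices over a hard clustering of rows of x.
ch_index <- function(x, cl) {
  n <- nrow(x); k <- length(unique(cl))
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (g in unique(cl)) {
    xg <- x[cl == g, , drop = FALSE]
    cg <- colMeans(xg)
    w <- w + sum(sweep(xg, 2, cg)^2)
    b <- b + nrow(xg) * sum((cg - grand)^2)
  }
  if (w == 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

db_index <- function(x, cl) {
  groups <- sort(unique(cl))
  k <- length(groups)
  cent <- t(vapply(groups, function(g) colMeans(x[cl == g, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_len(k), function(i) {
    xg <- x[cl == groups[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xg, 2, cent[i, ])^2)))
  }, numeric(1))
  r <- 0
  for (i in seq_len(k)) {
    rij <- vapply(setdiff(seq_len(k), i), function(j) {
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (d == 0) Inf else (s[i] + s[j]) / d
    }, numeric(1))
    r <- r + max(rij)
  }
  r / k
}

#' Choose the number of sample clusters by index voting
#'
#' Cuts the hierarchical tree at each candidate `k` and computes three
#' internal validity indices — mean silhouette width, Calinski-Harabasz,
#' and Davies-Bouldin (inverted, smaller is better). Each index votes for
#' its best `k`; the majority wins, with ties broken toward the smaller
#' `k`. This is a deterministic, desk-scale consensus in the spirit of
#' multi-index cluster-number selectors.
#'
#' @param x sample x gene matrix.
#' @param k_range candidate cluster counts.
#' @param linkage `"ward"` (Ward.D2), `"complete"` or `"average"`.
#' @return A list: `k` (chosen), `vote_table` (per-index preferred `k`),
#'   `index_table` (k x index values).
#' @export
choose_k <- function(x, k_range = 2:6, linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  k_range <- sort(unique(as.integer(k_range)))
  if (nrow(x) < max(k_range) + 1) {
    stop("need at least max(k_range) + 1 samples", call. = FALSE)
  }
  if (all(apply(x, 2, var) == 0)) {
    stop("degenerate input: all samples identical", call. = FALSE)
  }
  d <- dist(x)
  tree <- hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  idx <- matrix(NA_real_, nrow = length(k_range), ncol = 3,
                dimnames = list(k_range, c("silhouette", "calinski_harabasz",
                                           "davies_bouldin")))
  for (i in seq_along(k_range)) {
    cl <- cutree(tree, k = k_range[i])
    if (length(unique(cl)) < 2) next
    sil <- cluster::silhouette(cl, d)
    idx[i, "silhouette"] <- mean(sil[, "sil_width"])
    idx[i, "calinski_harabasz"] <- ch_index(x, cl)
    idx[i, "davies_bouldin"] <- db_index(x, cl)
  }
  best_of <- function(v, smaller_better = FALSE) {
    v_cmp <- if (smaller_better) -v else v
    k_range[which.max(v_cmp)]  # which.max takes the first (smallest k) on ties
  }
  votes <- c(silhouette = best_of(idx[, 1]),
             calinski_harabasz = best_of(idx[, 2]),
             davies_bouldin = best_of(idx[, 3], smaller_better = TRUE))
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k = min(winners), vote_table = votes, index_table = idx)
}

#' Cluster samples on key-gene methylation
#'
#' Agglomerative clustering of samples (rows) with the given linkage on
#' Euclidean distance; cluster labels are `"C1"`, `"C2"`, ... ordered by
#' decreasing cluster size (ties by first appearance in the cut).
#'
#' @param x sample x gene matrix (e.g. key-gene promoter means).
#' @param k number of clusters (from [choose_k()] or user-set).
#' @param linkage `"ward"`, `"complete"` or `"average"`.
#' @return A list of class `"subgroup_assignment"`: `subgroup` (named
#'   character vector sample -> label), `k`, `linkage`, `sizes`.
#' @export
cluster_samples <- function(x, k, linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  if (k > nrow(x)) stop("`k` exceeds the number of samples", call. = FALSE)
  tree <- hclust(dist(x), method = if (linkage == "ward") "ward.D2" else linkage)
  cl <- cutree(tree, k = k)
  sizes <- table(cl)
  ranked <- as.integer(names(sizes)[order(-sizes, as.integer(names(sizes)))])
  relabel <- stats::setNames(paste0("C", seq_along(ranked)), ranked)
  sub <- stats::setNames(unname(relabel[as.character(cl)]),
                         rownames(x) %||% paste0("s", seq_len(nrow(x))))
  structure(list(subgroup = sub, k = as.integer(k), linkage = linkage,
                 sizes = table(sub)),
            class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf("Subgroup assignment: %d samples in %d clusters (%s linkage)\n",
              length(x$subgroup), x$k, x$linkage))
  print(x$sizes)
  invisible(x)
}

# --- t-SNE (exact, quadratic) --------------------------------------------
# Small cohorts only; used for display, never for decisions.

tsne_p_matrix <- function(d2, perplexity) {
  n <- nrow(d2)
  p <- matrix(0, n, n)
  log_perp <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) {
        h <- 0
      } else {
        pj <- w / sw
        h <- -sum(ifelse(pj > 0, pj * log(pj), 0))
      }
      diff <- h - log_perp
      if (abs(diff) < 1e-5) break
      if (diff > 0) {        # entropy too high -> narrow the kernel
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-d2[i, ] * beta)
    w[i] <- 0
    p[i, ] <- if (sum(w) > 0) w / sum(w) else 0
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

#' 2-D stochastic neighbor embedding for display
#'
#' A compact exact t-SNE (quadratic in the number of samples, intended
#' for desk-scale cohorts): Gaussian input affinities calibrated to the
#' given perplexity, Student-t output kernel, gradient descent with
#' momentum and early exaggeration. Purely a visualization aid — nothing
#' downstream consumes the coordinates.
#'
#' @param x sample x feature matrix (at least 5 samples).
#' @param perplexity effective neighborhood size; capped at
#'   `(n - 1) / 3`.
#' @param n_iter gradient iterations.
#' @param seed integer seed (initial coordinates); fixed seed gives
#'   identical output.
#' @return A sample x 2 coordinate matrix.
#' @export
embed_2d <- function(x, perplexity = 10, n_iter = 300, seed = 1) {
  n <- nrow(x)
  if (n < 5) stop("need at least 5 samples", call. = FALSE)
  perplexity <- max(2, min(perplexity, floor((n - 1) / 3)))
  d2 <- as.matrix(dist(x))^2
  p <- tsne_p_matrix(d2, perplexity)
  with_local_seed(seed, {
    y <- matrix(rnorm(n * 2, sd = 1e-4), ncol = 2)
    inc <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    eta <- 100
    for (it in seq_len(n_iter)) {
      exag <- if (it <= 100) 4 else 1
      momentum <- if (it <= 20) 0.5 else 0.8
      yd2 <- as.matrix(dist(y))^2
      qnum <- 1 / (1 + yd2)
      diag(qnum) <- 0
      q <- pmax(qnum / sum(qnum), 1e-12)
      mult <- (exag * p - q) * qnum
      grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains <- pmax(gains, 0.01)
      inc <- momentum * inc - eta * gains * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    rownames(y) <- rownames(x)
    colnames(y) <- c("dim1", "dim2")
    y
  })
}
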