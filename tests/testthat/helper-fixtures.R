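# Shared fixture builders. Everything is generated in code at test time.

# Tiny probe annotation: one gene per strand with probes at hand-picked
# positions relative to the TSS.
toy_annotation <- function() {
  data.frame(
    probe_id = sprintf("cg%02d", 1:8),
    chrom = "chr1",
    pos = c(8000L, 10499L, 10000L, 10500L,   # + strand gene, tss 10000
            11999L, 12000L, 9501L, 9500L),   # - strand gene, tss 10000
    strand = c(rep("+", 4), rep("-", 4)),
    gene_symbol = rep(c("GPLUS", "GMINUS"), each = 4),
    tss = 10000L,
    stringsAsFactors = FALSE
  )
}

# Small complete beta matrix with named dims.
toy_beta <- function(n_probes = 6, n_samples = 8, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_probes * n_samples), nrow = n_probes,
                dimnames = list(sprintf("cg%02d", seq_len(n_probes)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  })
}

# Independent Benjamini-Hochberg oracle (direct definition).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Trapezoidal ROC-integration AUC oracle.
roc_trapezoid_auc <- function(scores, labels, positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- labels == positive
  tpr <- c(0, vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Naive O(n^3) topological overlap oracle.
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Hand log-rank statistic for two groups (observed-minus-expected form).
logrank_oracle_2g <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o1 - e1)^2 / v
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Least-squares deconvolution oracle: unconstrained fit, clip, renormalize.
ls_deconv_oracle <- function(bulk, sig) {
  t(apply(bulk, 2, function(y) {
    w <- coef(lm(y ~ sig + 0))
    w[w < 0] <- 0
    if (sum(w) == 0) w[] <- 1 / length(w)
    w / sum(w)
  }))
}

# Light pipeline settings used for replicated end-to-end sweeps: smaller
# forests and fewer selection iterations keep a full run near 7 s without
# changing what the pipeline does.
fit_preset <- function(preset, seed, n_trees = 400, boruta_max_iter = 60, ...) {
  spec <- luminal_preset(preset, seed = seed)
  co <- generate_cohort(spec)
  pw <- generate_pathways(co$truth, n_pathways = 20, overlap = 0.8, seed = seed)
  fit <- suppressWarnings(methylim(
    co$beta, co$annotation, pw, co$groups,
    min_module_size = 5, n_trees = n_trees,
    boruta_max_iter = boruta_max_iter, seed = seed, ...))
  list(fit = fit, cohort = co)
}
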