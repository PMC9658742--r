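# Builds a small labeled single-cell fixture with disjoint marker blocks.
block_cells <- function(n_types = 4, markers_per_type = 15, cells = 20,
                        base = 1, high = 30, noise = 0.2, seed = 1) {
  withr::with_seed(seed, {
    types <- paste0("T", seq_len(n_types))
    genes <- unlist(lapply(types, function(t) paste0(t, "_m", seq_len(markers_per_type))))
    expr <- matrix(base, nrow = length(genes), ncol = n_types * cells,
                   dimnames = list(genes, paste0("c", seq_len(n_types * cells))))
    labels <- stats::setNames(rep(types, each = cells), colnames(expr))
    for (t in types) {
      expr[grep(paste0("^", t, "_"), genes), labels == t] <- high
    }
    expr <- expr * matrix(exp(rnorm(length(expr), 0, noise)), nrow = nrow(expr))
    list(expr = expr, labels = labels, types = types)
  })
}

test_that("signature building recovers disjoint marker blocks exactly", {
  fx <- block_cells(seed = 2)
  sig <- build_signature(fx$expr, fx$labels)
  for (t in fx$types) {
    expect_setequal(sig$markers[[t]],
                    rownames(fx$expr)[grep(paste0("^", t, "_"), rownames(fx$expr))])
  }
  expect_true(all(rownames(sig$signature) %in% unlist(sig$markers)))
  expect_false(any(rowSums(sig$signature) == 0))
})

test_that("marker calls match a brute-force per-gene test", {
  fx <- block_cells(n_types = 3, markers_per_type = 8, cells = 12, seed = 3)
  sig <- build_signature(fx$expr, fx$labels, min_lfc = 1, max_p = 0.05)
  lx <- log1p(fx$expr)
  for (t in fx$types) {
    in_t <- fx$labels == t
    p <- apply(lx, 1, function(g) wilcox.test(g[in_t], g[!in_t])$p.value)
    lfc <- rowMeans(lx[, in_t]) - rowMeans(lx[, !in_t])
    oracle <- rownames(fx$expr)[p.adjust(p, "BH") < 0.05 & lfc >= 1]
    expect_setequal(sig$markers[[t]], oracle)
  }
})

test_that("indistinguishable cell types are rejected", {
  fx <- block_cells(n_types = 2, seed = 4)
  labels <- fx$labels
  # relabel half of each type so both "types" share one expression profile
  labels[] <- rep(c("X", "Y"), length.out = length(labels))
  expect_error(suppressWarnings(build_signature(fx$expr, labels)), "no marker")
})

test_that("nu-SVR deconvolution recovers mixtures on the simplex", {
  fx <- block_cells(n_types = 4, markers_per_type = 20, noise = 0.1, seed = 5)
  sig <- build_signature(fx$expr, fx$labels)
  s <- sig$signature

  # noiseless two-component mixture
  p_true <- c(0.3, 0.7, 0, 0)
  bulk <- matrix(s %*% p_true, ncol = 1,
                 dimnames = list(rownames(s), "mix1"))
  est <- deconvolve(bulk, sig)
  expect_equal(rowSums(est$proportions), 1, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(est$proportions[1, ] - p_true)), 0.02)

  # a pure signature column comes back one-hot
  pure <- matrix(s[, 2], ncol = 1, dimnames = list(rownames(s), "pure"))
  est2 <- deconvolve(pure, sig)
  expect_gt(est2$proportions[1, 2], 0.95)

  expect_error(deconvolve(matrix(1, 3, 1, dimnames = list(c("a", "b", "c"), "x")),
                          sig), "share no genes")
})

test_that("noisy mixtures are recovered within tolerance", {
  fx <- block_cells(n_types = 4, markers_per_type = 20, noise = 0.1, seed = 6)
  sig <- build_signature(fx$expr, fx$labels)
  s <- sig$signature
  withr::with_seed(7, {
    p_true <- t(apply(matrix(rgamma(50 * 4, 2), 50), 1, function(r) r / sum(r)))
    bulk <- s %*% t(p_true) + matrix(rnorm(nrow(s) * 50, sd = 0.1), nrow(s))
    bulk[bulk < 0] <- 0
    colnames(bulk) <- paste0("m", 1:50)
  })
  est <- deconvolve(bulk, sig)
  mae <- mean(abs(est$proportions - p_true))
  expect_lte(mae, 0.05)
  # under pure Gaussian noise least squares is the maximum-likelihood
  # fit; the SVR must stay within a hair of it
  ls <- ls_deconv_oracle(bulk, s)
  expect_lte(mae, mean(abs(ls - p_true)) + 0.005)
  expect_equal(rowSums(est$proportions), rep(1, 50), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the SVR beats clipped least squares under contamination", {
  fx <- block_cells(n_types = 4, markers_per_type = 20, noise = 0.1, seed = 16)
  sig <- build_signature(fx$expr, fx$labels)
  s <- sig$signature
  withr::with_seed(17, {
    p_true <- t(apply(matrix(rgamma(50 * 4, 2), 50), 1, function(r) r / sum(r)))
    bulk <- s %*% t(p_true) + matrix(rnorm(nrow(s) * 50, sd = 0.1), nrow(s))
    mask <- matrix(runif(length(bulk)) < 0.05, nrow(bulk))
    bulk[mask] <- bulk[mask] * 3  # 5% of entries blown up
    bulk[bulk < 0] <- 0
    colnames(bulk) <- paste0("m", 1:50)
  })
  est <- deconvolve(bulk, sig)
  mae <- mean(abs(est$proportions - p_true))
  ls <- ls_deconv_oracle(bulk, s)
  expect_lte(mae, mean(abs(ls - p_true)))
  expect_lte(mae, 0.05)
})

test_that("per-type pseudo-bulk deconvolves to near one-hot proportions", {
  fx <- block_cells(n_types = 4, markers_per_type = 15, noise = 0.15, seed = 8)
  sig <- build_signature(fx$expr, fx$labels)
  pseudo <- vapply(fx$types, function(t) {
    rowSums(fx$expr[rownames(sig$signature), fx$labels == t])
  }, numeric(nrow(sig$signature)))
  est <- deconvolve(pseudo, sig)
  for (i in seq_along(fx$types)) {
    off <- est$proportions[i, -i]
    expect_lte(max(off), 0.05)
  }
})

test_that("deconvolution ignores a positive rescaling of the bulk profile", {
  fx <- block_cells(n_types = 3, seed = 9)
  sig <- build_signature(fx$expr, fx$labels)
  bulk <- matrix(sig$signature %*% c(0.2, 0.5, 0.3), ncol = 1,
                 dimnames = list(rownames(sig$signature), "m"))
  e1 <- deconvolve(bulk, sig)$proportions
  e2 <- deconvolve(bulk * 37, sig)$proportions
  expect_equal(e1, e2, tolerance = 1e-8)
})

test_that("cytolytic activity is the exact effector mean and tracks truth", {
  bulk <- matrix(c(4, 0, 6, 0, 1, 2), nrow = 3, byrow = TRUE,
                 dimnames = list(c("GZMA", "PRF1", "OTHER"), c("s1", "s2")))
  expect_equal(unname(compute_cyt(bulk)), c((4 + 6) / 2, 0))
  zero <- bulk; zero[1:2, ] <- 0
  expect_equal(unname(compute_cyt(zero)), c(0, 0))
  expect_error(compute_cyt(bulk[3, , drop = FALSE]), "GZMA")

  co <- generate_cohort(cohort_spec(seed = 10))
  bulk2 <- generate_bulk_expression(co$truth, noise_sd = 0.1, seed = 2)
  cyt <- compute_cyt(bulk2)
  rho <- cor(cyt, co$truth$true_proportions[names(cyt), "T_cells"],
             method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("entropy specificity flags concentrated, significant genes", {
  m <- rbind(gene_a = c(0.9, 0.1))
  h <- methylation_specificity(m, c(gene_a = 0.01), entropy_quantile = 1)
  expect_equal(h$entropy, 0.469, tolerance = 1e-3)

  k <- 4
  flat <- matrix(0.5, nrow = 50, ncol = k,
                 dimnames = list(paste0("g", 1:50), paste0("S", 1:k)))
  expect_equal(methylation_specificity(flat, stats::setNames(rep(0.001, 50),
                                                             rownames(flat)))$entropy,
               rep(log2(k), 50))

  # one planted subgroup-specific gene among flat ones
  mm <- flat
  mm["g7", ] <- c(0.9, 0.05, 0.05, 0.05)
  kw <- stats::setNames(rep(0.5, 50), rownames(mm))
  kw["g7"] <- 0.001
  res <- methylation_specificity(mm, kw)
  expect_true(res$specific[res$gene == "g7"])
  expect_identical(sum(res$specific), 1L)

  # all-zero gene: maximal entropy, never specific
  mm["g9", ] <- 0
  res2 <- methylation_specificity(mm, kw)
  expect_equal(res2$entropy[res2$gene == "g9"], 2)
  expect_false(res2$specific[res2$gene == "g9"])
})
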