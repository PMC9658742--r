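test_that("promoter windows are strand-aware and half-open", {
  ann <- toy_annotation()
  hits <- promoter_probes(ann)
  # + strand, tss 10000: [8000, 10500)
  expect_true(all(c("cg01", "cg02", "cg03") %in% hits))  # 8000, 10499, tss
  expect_false("cg04" %in% hits)                         # 10500 excluded
  # - strand, tss 10000: (9500, 12000]
  expect_true(all(c("cg05", "cg06", "cg07") %in% hits))  # 11999, 12000, 9501
  expect_false("cg08" %in% hits)                         # 9500 excluded
  # probe exactly at the TSS is included on both strands
  ann2 <- ann
  ann2$pos[5] <- 10000L
  expect_true("cg05" %in% promoter_probes(ann2))

  ann$strand[2] <- "*"
  expect_error(promoter_probes(ann), "cg02")
})

test_that("missingness filter drops strictly-exceeding probes only", {
  m <- matrix(1, nrow = 3, ncol = 10,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:10)))
  m[1, 1:6] <- NA  # 6/10 -> dropped
  m[2, 1:5] <- NA  # 5/10 -> kept ("exceeding" is strict)
  out <- suppressMessages(filter_missingness(m))
  expect_identical(rownames(out), c("p2", "p3"))
  expect_identical(attr(out, "n_dropped"), 1L)

  full <- toy_beta()
  expect_equal(suppressMessages(filter_missingness(full)), full,
               ignore_attr = TRUE)

  all_bad <- matrix(NA_real_, 2, 4)
  expect_error(filter_missingness(all_bad), "all probes")
})

test_that("missingness filter matches an independent per-probe recount", {
  co <- generate_cohort(cohort_spec(missing_rate = 0.1, seed = 9))
  kept <- rownames(suppressMessages(filter_missingness(co$beta, 0.5)))
  manual <- rownames(co$beta)[
    vapply(seq_len(nrow(co$beta)),
           function(i) sum(is.na(co$beta[i, ])) / ncol(co$beta) <= 0.5,
           logical(1))]
  expect_identical(kept, manual)
})

test_that("KNN imputation uses nearest probes and is idempotent", {
  m <- toy_beta(6, 8)
  m <- rbind(m, dup = m[1, ])  # exact duplicate of probe 1
  m_holes <- m
  m_holes["dup", 3] <- NA
  out <- knn_impute(m_holes, k = 1)
  expect_equal(out["dup", 3], m[1, 3])  # zero-distance neighbor wins

  const <- matrix(0.4, 5, 6, dimnames = list(paste0("p", 1:5), paste0("s", 1:6)))
  const[2, 4] <- NA
  expect_equal(unname(knn_impute(const, 2)[2, 4]), 0.4)

  # complete matrix -> identity
  expect_identical(knn_impute(m, 3), m)
  expect_error(knn_impute(m, k = nrow(m)), "smaller")
  bad <- m
  bad[2, ] <- NA
  expect_error(knn_impute(bad, 2), "observed value")
})

test_that("KNN imputation beats column-mean imputation on correlated data", {
  co <- generate_cohort(cohort_spec(missing_rate = 0, seed = 13))
  beta <- co$beta
  withr::with_seed(1, {
    idx <- cbind(sample(nrow(beta), 50, replace = TRUE),
                 sample(ncol(beta), 50, replace = TRUE))
  })
  idx <- idx[!duplicated(idx), , drop = FALSE]
  truth <- beta[idx]
  holed <- beta
  holed[idx] <- NA
  imp <- knn_impute(holed, 10)
  col_means <- colMeans(holed, na.rm = TRUE)
  mae_knn <- mean(abs(imp[idx] - truth))
  mae_col <- mean(abs(col_means[idx[, 2]] - truth))
  expect_lt(mae_knn, mae_col)
  expect_false(anyNA(imp))
  expect_true(all(imp >= 0 & imp <= 1))
})

test_that("differential calling handles forced and degenerate cases", {
  m <- matrix(c(rep(0.9, 5), rep(0.5, 5),
                rep(0.3, 10)), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), paste0("s", 1:10)))
  dt <- call_differential(m, paste0("s", 1:5), paste0("s", 6:10))
  expect_equal(dt$beta_d[1], 0.4, tolerance = 1e-12)
  expect_true(dt$is_differential[1])
  # identical groups: beta_d 0, zero variance -> p = 1, not flagged
  expect_equal(dt$beta_d[2], 0)
  expect_equal(dt$p_value[2], 1)
  expect_false(dt$is_differential[2])

  expect_error(call_differential(m, paste0("s", 1:5), paste0("s", 5:10)),
               "overlap")
  expect_error(call_differential(m, "s1", paste0("s", 6:10)), "at least 2")
})

test_that("differential p-values match the t oracle and BH the manual sort", {
  beta <- toy_beta(50, 20, seed = 3)
  cases <- paste0("s", sprintf("%02d", 1:10))
  controls <- paste0("s", sprintf("%02d", 11:20))
  dt <- call_differential(beta, cases, controls, min_abs_bd = 0.1, max_fdr = 0.2)
  p_oracle <- apply(beta, 1, function(r) {
    t.test(r[cases], r[controls], var.equal = TRUE)$p.value
  })
  expect_equal(dt$p_value, unname(p_oracle), tolerance = 1e-9)
  expect_equal(dt$fdr, bh_oracle(dt$p_value), tolerance = 1e-12)
  manual_flag <- abs(dt$beta_d) >= 0.1 & bh_oracle(dt$p_value) < 0.2
  expect_identical(dt$is_differential, manual_flag)

  # Welch variant agrees with R's default t.test
  dtw <- call_differential(beta, cases, controls, var_equal = FALSE)
  pw <- apply(beta, 1, function(r) t.test(r[cases], r[controls])$p.value)
  expect_equal(dtw$p_value, unname(pw), tolerance = 1e-9)
})

test_that("differential calling is invariant to row and column order", {
  beta <- toy_beta(30, 12, seed = 5)
  cases <- colnames(beta)[1:6]
  controls <- colnames(beta)[7:12]
  dt1 <- call_differential(beta, cases, controls)
  perm <- beta[sample(nrow(beta)), sample(ncol(beta))]
  dt2 <- call_differential(perm, cases, controls)
  dt2 <- dt2[match(dt1$probe_id, dt2$probe_id), ]
  expect_equal(dt1$p_value, dt2$p_value, tolerance = 1e-12)
  expect_equal(dt1$fdr, dt2$fdr, tolerance = 1e-12)
})

test_that("flagged sites map to deduplicated gene sets", {
  dt <- data.frame(probe_id = c("a", "b", "c"),
                   gene_symbol = c("G1", "G1", "G2"),
                   is_differential = c(TRUE, TRUE, FALSE))
  expect_identical(sites_to_genes(dt), "G1")
  dt$is_differential <- FALSE
  expect_identical(sites_to_genes(dt), character(0))
})

test_that("a noiseless cohort recovers exactly the planted key genes", {
  spec <- cohort_spec(missing_rate = 0, beta_noise = 1e6, latent_sd = 0,
                      wide_latent_sd = 0, seed = 21)
  co <- generate_cohort(spec)
  tum <- names(co$groups)[co$groups == "tumor"]
  nor <- names(co$groups)[co$groups == "normal"]
  dt <- call_differential(co$beta, tum, nor, ann = co$annotation)
  expect_setequal(sites_to_genes(dt), co$truth$key_gene_ids)
})

test_that("promoter gene means average the right probes", {
  ann <- toy_annotation()
  beta <- matrix(seq(0.1, 0.8, length.out = 8), nrow = 8, ncol = 2,
                 dimnames = list(ann$probe_id, c("s1", "s2")))
  gm <- promoter_gene_means(beta, ann)
  # GPLUS promoter probes: cg01..cg03; GMINUS: cg05..cg07
  expect_equal(gm["GPLUS", "s1"], mean(beta[c("cg01", "cg02", "cg03"), "s1"]))
  expect_equal(gm["GMINUS", "s1"], mean(beta[c("cg05", "cg06", "cg07"), "s1"]))
})
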