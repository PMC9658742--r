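test_that("cohort spec validation rejects impossible designs", {
  expect_error(cohort_spec(n_subgroups = 1), "at least 2")
  expect_error(cohort_spec(subgroup_props = c(0.6, 0.6)), "sum to 1")
  expect_error(cohort_spec(delta_beta = 0), "delta_beta")
  expect_error(cohort_spec(missing_rate = 0.6), "drop every probe")
  expect_error(cohort_spec(n_probes = 50, n_key_genes = 30), "too small")
})

test_that("generated cohorts have in-range values and planted contrasts", {
  spec <- cohort_spec(missing_rate = 0, seed = 42)
  co <- generate_cohort(spec)
  expect_true(all(co$beta >= 0 & co$beta <= 1))
  expect_identical(dim(co$beta), c(500L, 60L))

  # every key-gene promoter probe clears the calling threshold on average
  tum <- names(co$groups)[co$groups == "tumor"]
  nor <- names(co$groups)[co$groups == "normal"]
  key_probes <- co$annotation$probe_id[
    co$annotation$gene_symbol %in% co$truth$key_gene_ids]
  shift <- abs(rowMeans(co$beta[key_probes, tum]) -
                 rowMeans(co$beta[key_probes, nor]))
  expect_true(all(shift >= 0.2))

  # subgroup proportions honored
  expect_equal(unname(table(co$truth$subgroup_of_sample)),
               unname(table(rep(c("S1", "S2"), each = 20))))
  # proportions ground truth on the simplex
  expect_equal(unname(rowSums(co$truth$true_proportions)),
               rep(1, nrow(co$truth$true_proportions)), tolerance = 1e-9)
})

test_that("generation is bitwise reproducible from the seed", {
  a <- generate_cohort(cohort_spec(seed = 7))
  b <- generate_cohort(cohort_spec(seed = 7))
  expect_identical(a, b)
  expect_false(identical(a$beta, generate_cohort(cohort_spec(seed = 8))$beta))
})

test_that("missingness lands at the requested rate", {
  co <- generate_cohort(cohort_spec(n_probes = 500, missing_rate = 0.1, seed = 5))
  expect_lt(abs(mean(is.na(co$beta)) - 0.1), 0.02)
})

test_that("pathway generation concentrates cancer pathways on planted genes", {
  co <- generate_cohort(cohort_spec(seed = 3))
  pw <- generate_pathways(co$truth, n_pathways = 20, overlap = 0.8, seed = 3)
  expect_s3_class(pw, "pathway_collection")
  expect_length(pw$pathways, 20)

  cancer_pool <- names(co$truth$planted_module_of_gene)[
    co$truth$planted_module_of_gene %in% co$truth$cancer_module_ids]
  enr <- enrich_pathways(cancer_pool, pw)
  best <- enr$pathway_id[which.min(enr$p_value)]
  expect_true(best %in% pw$cancer_related_ids)

  # overlap = 0: planted genes at background rate (frequency over many sets)
  pw0 <- generate_pathways(co$truth, n_pathways = 200, overlap = 0, seed = 4)
  frac <- mean(unlist(pw0$pathways) %in% co$truth$key_gene_ids)
  bg <- length(co$truth$key_gene_ids) / length(co$truth$gene_universe)
  expect_lt(abs(frac - bg), 0.05)

  # n_pathways = 0: empty collection that still round-trips as GMT
  pw_empty <- generate_pathways(co$truth, n_pathways = 0, seed = 1)
  f <- tempfile(fileext = ".gmt")
  write_gmt(pw_empty, f)
  expect_length(read_gmt_pathways(f)$pathways, 0)

  expect_error(generate_pathways(co$truth, n_pathways = 5, overlap = 1,
                                 size_range = c(40L, 50L), seed = 1),
               "more cancer-module genes")
})

test_that("single cells are labeled draws around the signature", {
  co <- generate_cohort(cohort_spec(seed = 2))
  sc <- generate_single_cell(co$truth, cells_per_type = 50, dispersion = 1e-12,
                             seed = 2)
  expect_identical(ncol(sc$expr), 250L)  # 5 types x 50 cells
  # dispersion -> 0: per-type mean equals the signature column
  for (t in colnames(co$truth$true_signature)) {
    expect_equal(rowMeans(sc$expr[, sc$labels == t]),
                 co$truth$true_signature[, t], tolerance = 1e-8)
  }
  expect_identical(generate_single_cell(co$truth, 10, 0.3, seed = 9),
                   generate_single_cell(co$truth, 10, 0.3, seed = 9))
  expect_error(generate_single_cell(co$truth, cells_per_type = 1), "at least 2")
})

test_that("bulk expression is the stated mixture plus noise", {
  co <- generate_cohort(cohort_spec(seed = 6))
  truth <- co$truth
  bulk0 <- generate_bulk_expression(truth, noise_sd = 0, seed = 1)
  expect_equal(bulk0, truth$true_signature %*% t(truth$true_proportions),
               tolerance = 1e-12, ignore_attr = TRUE)

  # one-hot proportions reproduce a signature column exactly
  t1 <- truth
  t1$true_proportions <- matrix(c(1, 0, 0, 0, 0), nrow = 1,
                                dimnames = list("X1", colnames(truth$true_signature)))
  b1 <- generate_bulk_expression(t1, noise_sd = 0, seed = 1)
  expect_equal(b1[, 1], truth$true_signature[, 1], ignore_attr = TRUE)

  # residual standard deviation tracks noise_sd (clipping is negligible)
  bulk <- generate_bulk_expression(truth, noise_sd = 0.1, seed = 3)
  res <- bulk - truth$true_signature %*% t(truth$true_proportions)
  expect_lt(abs(sd(as.vector(res)) - 0.1) / 0.1, 0.2)
  expect_true(all(bulk >= 0))
})

test_that("survival tables honor censoring and subgroup hazards", {
  co <- generate_cohort(cohort_spec(seed = 4))
  cl0 <- generate_survival(co$truth, censor_rate = 0, seed = 1)
  expect_true(all(cl0$event == 1))
  expect_identical(sort(names(table(cl0$subgroup))), c("S1", "S2"))
  expect_true(all(c("stage_T", "stage_N", "stage_M", "tils_type") %in% names(cl0)))
  expect_true(all(cl0$tils_type %in% c("brisk band-like", "brisk diffuse",
                                       "non-brisk focal", "non-brisk multifocal")))
  cl <- generate_survival(co$truth, censor_rate = 0.3, seed = 2)
  expect_lt(abs(mean(cl$event == 0) - 0.3), 0.2)
  expect_identical(generate_survival(co$truth, seed = 5),
                   generate_survival(co$truth, seed = 5))
  expect_error(generate_survival(co$truth, hazard_by_subgroup = c(S1 = -1, S2 = 1)),
               "positive")
})

test_that("ground truth round-trips losslessly through JSON", {
  co <- generate_cohort(cohort_spec(seed = 11))
  f <- tempfile(fileext = ".json")
  write_ground_truth(co$truth, f)
  back <- read_ground_truth(f)
  expect_equal(back, co$truth, tolerance = 1e-12)
})

test_that("block matrix simulator hits the requested correlation structure", {
  sim <- simulate_module_matrix(n_modules = 3, genes_per_module = 40,
                                n_samples = 60, intra_cor = 0.8, seed = 1)
  cc <- cor(t(sim$x))
  same <- outer(sim$module, sim$module, "==") & row(cc) != col(cc)
  expect_lt(abs(mean(cc[same]) - 0.8), 0.06)
  expect_lt(mean(abs(cc[!same & row(cc) != col(cc)])), 0.25)
  expect_true(all(sim$x > 0 & sim$x < 1))
})
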