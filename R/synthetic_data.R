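# Synthetic cohort generator.
#
# Emits every input the subgrouping pipeline consumes — a probe x sample
# beta matrix with missingness, a 450K-manifest-like probe annotation,
# pathway gene sets, labeled single cells, bulk expression mixtures and a
# clinical table — with planted subgroup structure so each stage can be
# verified against ground truth.

#' Specify a synthetic methylation cohort
#'
#' Describes a tumor/normal cohort with `n_subgroups` planted tumor
#' subgroups. Each key gene carries promoter probes whose tumor mean beta is
#' shifted by `+/- delta_beta` relative to normals according to a
#' per-module sign pattern over subgroups; key genes are partitioned into
#' `n_modules` co-methylation modules tied together by a shared latent
#' factor of standard deviation `latent_sd`. All other probes share one
#' (bimodal, array-like) beta distribution across every sample.
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_subgroups number of planted tumor subgroups (k >= 2).
#' @param subgroup_props mixing proportions over subgroups (sums to 1).
#' @param n_probes total probe count (key-gene promoter probes included).
#' @param n_key_genes number of planted key genes.
#' @param n_modules number of planted co-methylation modules among key genes.
#' @param delta_beta absolute mean beta shift of key promoter probes in
#'   tumors versus normals, in (0, 1].
#' @param beta_noise concentration (shape1 + shape2) of the beta-distributed
#'   measurement noise; larger is less noisy. The default 6 gives a
#'   per-probe standard deviation of about 0.15 at mid-range means, so
#'   single probes are noisy (correlating below the default
#'   collinearity-pruning threshold even within a planted module) while
#'   gene-level promoter means remain clean — the regime methylation
#'   arrays actually live in.
#' @param latent_sd standard deviation of the per-module shared latent
#'   factor that induces co-methylation in the subgroup-informative
#'   modules.
#' @param wide_latent_sd latent-factor standard deviation of the last,
#'   tumor-wide module, which has no subgroup variance and coheres only
#'   through its shared (methylator-phenotype-like) factor.
#' @param probes_per_key_gene promoter probes per key gene.
#' @param missing_rate fraction of entries set missing completely at random,
#'   in \[0, 0.5\] (beyond 0.5 every probe would fail the missingness filter
#'   in expectation).
#' @param cell_types cell-type labels of the expression ground truth; must
#'   include a cytotoxic type named `"T_cells"`.
#' @param seed integer seed; fixing it fixes every generated artifact.
#' @return An object of class `"cohort_spec"`.
#' @seealso [generate_cohort()], [luminal_preset()]
#' @export
cohort_spec <- function(n_tumor = 40, n_normal = 20, n_subgroups = 2,
                        subgroup_props = NULL, n_probes = 500,
                        n_key_genes = 30, n_modules = 3, delta_beta = 0.3,
                        beta_noise = 6, latent_sd = 0.05, wide_latent_sd = 0.12,
                        probes_per_key_gene = 3, missing_rate = 0.05,
                        cell_types = c("T_cells", "B_cells", "Macrophage",
                                       "Epithelial", "Stromal"),
                        seed = 1) {
  for (nm in c("n_tumor", "n_normal", "n_subgroups", "n_probes",
               "n_key_genes", "n_modules", "probes_per_key_gene")) {
    stopifnot_scalar_count(get(nm), nm)
  }
  if (n_subgroups < 2) stop("`n_subgroups` must be at least 2", call. = FALSE)
  if (is.null(subgroup_props)) subgroup_props <- rep(1 / n_subgroups, n_subgroups)
  if (length(subgroup_props) != n_subgroups) {
    stop("`subgroup_props` must have one entry per subgroup", call. = FALSE)
  }
  if (abs(sum(subgroup_props) - 1) > 1e-9 || any(subgroup_props <= 0)) {
    stop("`subgroup_props` must be positive and sum to 1", call. = FALSE)
  }
  if (delta_beta <= 0 || delta_beta > 1) {
    stop("`delta_beta` must lie in (0, 1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 0.9) {
    stop("`missing_rate` must lie in [0, 0.9]", call. = FALSE)
  }
  if (missing_rate > 0.5) {
    stop("`missing_rate` above 0.5 would drop every probe at the default ",
         "missingness filter; no usable fixture can be generated", call. = FALSE)
  }
  if (n_probes < n_key_genes * probes_per_key_gene + 2) {
    stop("`n_probes` too small for the requested key genes", call. = FALSE)
  }
  if (length(cell_types) < 2 || !"T_cells" %in% cell_types) {
    stop("`cell_types` must contain at least 2 types including 'T_cells'",
         call. = FALSE)
  }
  structure(
    list(n_tumor = n_tumor, n_normal = n_normal, n_subgroups = n_subgroups,
         subgroup_props = subgroup_props, n_probes = n_probes,
         n_key_genes = n_key_genes, n_modules = n_modules,
         delta_beta = delta_beta, beta_noise = beta_noise,
         latent_sd = latent_sd, wide_latent_sd = wide_latent_sd,
         probes_per_key_gene = probes_per_key_gene,
         missing_rate = missing_rate, cell_types = cell_types,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Preset cohort specifications mirroring luminal A/B subgrouping
#'
#' Two desk-scale presets: `"A"` plants k = 2 subgroups (as found for
#' luminal A) with 3 co-methylation modules, and `"B"` plants k = 3
#' (luminal B) with 4 modules -- one subgroup-informative module per
#' subgroup plus the tumor-wide one. Both use 40 tumors, 20 normals,
#' 500 probes and 30 key genes.
#'
#' @param which `"A"` or `"B"`.
#' @param seed integer seed.
#' @param ... overrides passed on to [cohort_spec()].
#' @return A `"cohort_spec"`.
#' @export
luminal_preset <- function(which = c("A", "B"), seed = 1, ...) {
  which <- match.arg(which)
  if (which == "A") {
    cohort_spec(n_subgroups = 2, subgroup_props = c(0.5, 0.5), seed = seed, ...)
  } else {
    cohort_spec(n_subgroups = 3, subgroup_props = c(0.4, 0.35, 0.25),
                n_modules = 4, seed = seed, ...)
  }
}

# Sign pattern of module m over subgroups. Modules 1 .. n_modules - 1 are
# subgroup-informative: module m carries a strong (+) shift in its defining
# subgroup ((m - 1) mod k) + 1 and a weak (-) shift elsewhere, so any two
# subgroups differ on at least one module when n_modules > k. The last
# module is tumor-wide (+ in every subgroup, no subgroup information),
# giving the pipeline a module it should score low and leave out.
module_sign_pattern <- function(n_modules, k) {
  sgn <- matrix(-1, nrow = n_modules, ncol = k)
  for (m in seq_len(n_modules)) {
    if (m == n_modules && n_modules > 1) {
      sgn[m, ] <- 1
    } else {
      sgn[m, ((m - 1) %% k) + 1] <- 1
    }
  }
  sgn
}

#' Generate a synthetic methylation cohort with planted subgroups
#'
#' Draws a probe x sample beta matrix, a probe annotation with promoter
#' coordinates, and the ground truth of the planted structure. Key-gene
#' promoter probes are hypomethylated in normals (mean beta 0.15) and
#' hypermethylated in every tumor; the shift is `delta_beta` or
#' `2 * delta_beta` following the per-module sign pattern over subgroups,
#' so each key probe clears a `delta_beta`-sized tumor-versus-normal
#' contrast while the single/double difference distinguishes the
#' subgroups. The last planted module is tumor-wide (shifted equally in
#' every subgroup) and carries no subgroup information; the
#' subgroup-informative modules are recorded as the cancer modules of the
#' ground truth. Probes of a module share a per-sample latent factor,
#' which induces the co-methylation the module detector looks for.
#' Background probes draw from one bimodal beta distribution in every
#' sample. Missing entries are injected completely at random.
#'
#' The ground truth also carries the expression-side truth used by the
#' deconvolution tools: a gene x cell-type signature (with reserved
#' cytotoxic markers `GZMA` and `PRF1` plus checkpoint genes `PDCD1` and
#' `CD274` loaded on T cells) and per-tumor-sample true cell-type
#' proportions whose T-cell fraction decreases from the first planted
#' subgroup to the last.
#'
#' @param spec a [cohort_spec()].
#' @return A list with components `beta` (probe x sample matrix, `NA` for
#'   missing), `annotation` (data frame: `probe_id`, `chrom`, `pos`,
#'   `strand`, `gene_symbol`, `tss`), `groups` (named vector,
#'   `"tumor"`/`"normal"`), and `truth` (class `"ground_truth"`: subgroup
#'   labels, key gene ids, gene -> module map, cancer-module ids, true
#'   proportions and signature).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    k <- spec$n_subgroups
    n_t <- spec$n_tumor
    n_n <- spec$n_normal
    tumor_ids <- sprintf("T%03d", seq_len(n_t))
    normal_ids <- sprintf("N%03d", seq_len(n_n))
    samples <- c(tumor_ids, normal_ids)

    # subgroup assignment with sizes proportional to subgroup_props
    sizes <- diff(c(0, round(cumsum(spec$subgroup_props) * n_t)))
    subgroup <- rep(seq_len(k), times = sizes)
    names(subgroup) <- tumor_ids

    # gene / probe layout: key genes first, then 2-probe background genes
    key_genes <- sprintf("KG%03d", seq_len(spec$n_key_genes))
    n_key_probes <- spec$n_key_genes * spec$probes_per_key_gene
    n_bg_probes <- spec$n_probes - n_key_probes
    n_bg_genes <- ceiling(n_bg_probes / 2)
    bg_genes <- sprintf("BG%03d", seq_len(n_bg_genes))
    gene_of_probe <- c(rep(key_genes, each = spec$probes_per_key_gene),
                       rep(bg_genes, each = 2)[seq_len(n_bg_probes)])
    probe_ids <- sprintf("cg%05d", seq_len(spec$n_probes))
    genes <- c(key_genes, bg_genes)
    tss <- stats::setNames(10000L * seq_along(genes), genes)
    strand <- stats::setNames(sample(c("+", "-"), length(genes), replace = TRUE),
                              genes)
    # probe offsets kept inside the promoter window on either strand
    offset <- sample(-1500:400, spec$n_probes, replace = TRUE)
    pos <- ifelse(strand[gene_of_probe] == "+",
                  tss[gene_of_probe] + offset,
                  tss[gene_of_probe] - offset)
    annotation <- data.frame(
      probe_id = probe_ids, chrom = "chr1", pos = as.integer(pos),
      strand = unname(strand[gene_of_probe]),
      gene_symbol = gene_of_probe, tss = unname(tss[gene_of_probe]),
      stringsAsFactors = FALSE
    )

    # planted modules over key genes
    module_of_gene <- stats::setNames(
      rep(seq_len(spec$n_modules), length.out = spec$n_key_genes)[
        order(rep(seq_len(spec$n_modules), length.out = spec$n_key_genes))],
      key_genes
    )
    sgn <- module_sign_pattern(spec$n_modules, k)

    # mean matrix
    mu <- matrix(0, nrow = spec$n_probes, ncol = length(samples),
                 dimnames = list(probe_ids, samples))
    # background probes: one bimodal distribution shared by all samples
    bg_rows <- (n_key_probes + 1):spec$n_probes
    hyper <- runif(length(bg_rows)) < 0.5
    bg_mean <- ifelse(hyper, rbeta(length(bg_rows), 8, 2),
                      rbeta(length(bg_rows), 2, 8))
    mu[bg_rows, ] <- bg_mean
    # Key probes are hypomethylated in normals (0.15) and hypermethylated
    # in every tumor: the shift is delta_beta in (-)-pattern subgroups and
    # 2 * delta_beta in (+)-pattern ones, so every key probe clears the
    # tumor-vs-normal calling threshold while the single/double contrast
    # carries the subgroup signal.
    key_rows <- seq_len(n_key_probes)
    mu[key_rows, normal_ids] <- 0.15
    for (s in seq_len(k)) {
      cols <- tumor_ids[subgroup == s]
      sgn_s <- sgn[module_of_gene[gene_of_probe[key_rows]], s]
      shift <- spec$delta_beta * (1.5 + 0.5 * sgn_s)
      mu[key_rows, cols] <- 0.15 + shift
    }
    # Shared latent factor per module per sample (co-methylation). The
    # subgroup-informative modules cohere mostly through their subgroup
    # patterns and need only a mild latent factor; the tumor-wide module
    # has no subgroup variance and carries a stronger one (a CIMP-like
    # methylator factor), so it still forms a detectable module.
    for (m in seq_len(spec$n_modules)) {
      rows <- key_rows[module_of_gene[gene_of_probe[key_rows]] == m]
      lsd <- if (m == spec$n_modules && spec$n_modules > 1) {
        spec$wide_latent_sd
      } else {
        spec$latent_sd
      }
      f <- rnorm(length(samples), 0, lsd)
      mu[rows, ] <- mu[rows, ] + rep(f, each = length(rows))
    }
    mu <- clamp(mu, 0.02, 0.98)

    beta <- matrix(
      rbeta_mean_conc(length(mu), as.vector(mu), spec$beta_noise),
      nrow = nrow(mu), dimnames = dimnames(mu)
    )
    if (spec$missing_rate > 0) {
      beta[runif(length(beta)) < spec$missing_rate] <- NA_real_
    }

    groups <- stats::setNames(
      c(rep("tumor", n_t), rep("normal", n_n)), samples
    )

    # expression-side ground truth
    ct <- spec$cell_types
    reserved <- c("GZMA", "PRF1", "PDCD1", "CD274")
    sig_genes <- c(
      reserved,
      unlist(lapply(ct, function(t) sprintf("MK_%s_%02d", t, 1:20)))
    )
    signature <- matrix(1, nrow = length(sig_genes), ncol = length(ct),
                        dimnames = list(sig_genes, ct))
    for (t in ct) {
      rows <- sprintf("MK_%s_%02d", t, 1:20)
      signature[rows, t] <- runif(20, 20, 50)
    }
    signature[reserved, "T_cells"] <- c(30, 30, 20, 20)

    # per-subgroup Dirichlet: T-cell fraction decreases across subgroups
    grad <- (subgroup - 1) / (k - 1)
    alpha_T <- 10 - 6 * grad
    alpha_E <- 4 + 6 * grad
    props <- matrix(0, nrow = n_t, ncol = length(ct),
                    dimnames = list(tumor_ids, ct))
    for (i in seq_len(n_t)) {
      alpha <- rep(3, length(ct))
      names(alpha) <- ct
      alpha["T_cells"] <- alpha_T[i]
      if ("Epithelial" %in% ct) alpha["Epithelial"] <- alpha_E[i]
      props[i, ] <- rdirichlet(1, alpha)
    }

    truth <- structure(
      list(
        subgroup_of_sample = stats::setNames(paste0("S", subgroup), tumor_ids),
        key_gene_ids = key_genes,
        planted_module_of_gene = module_of_gene,
        cancer_module_ids = seq_len(max(1L, spec$n_modules - 1L)),
        gene_universe = genes,
        true_proportions = props,
        true_signature = signature,
        n_subgroups = as.integer(k)
      ),
      class = "ground_truth"
    )

    list(beta = beta, annotation = annotation, groups = groups, truth = truth)
  })
}

#' Simulate a block-correlated gene matrix for module detection
#'
#' Draws a gene x sample matrix of planted co-methylation blocks: genes of
#' block m are `sqrt(intra_cor) * f_m + sqrt(1 - intra_cor) * noise` for a
#' per-sample standard normal factor `f_m`, giving expected pairwise
#' correlation `intra_cor` within a block and 0 across blocks. Values are
#' mapped through the normal CDF so they lie in (0, 1) like beta values
#' (a monotone map that preserves the rank correlation structure).
#'
#' @param n_modules number of planted blocks.
#' @param genes_per_module genes per block.
#' @param n_samples samples (columns).
#' @param intra_cor expected within-block correlation, in \[0, 1).
#' @param seed integer seed.
#' @return A list: `x` (gene x sample matrix) and `module` (named integer
#'   vector gene -> planted block).
#' @export
simulate_module_matrix <- function(n_modules = 3, genes_per_module = 40,
                                   n_samples = 40, intra_cor = 0.8, seed = 1) {
  if (intra_cor < 0 || intra_cor >= 1) {
    stop("`intra_cor` must lie in [0, 1)", call. = FALSE)
  }
  with_local_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_modules * genes_per_module))
    module <- stats::setNames(rep(seq_len(n_modules), each = genes_per_module),
                              genes)
    x <- matrix(0, nrow = length(genes), ncol = n_samples,
                dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
    for (m in seq_len(n_modules)) {
      f <- rnorm(n_samples)
      rows <- which(module == m)
      eps <- matrix(rnorm(length(rows) * n_samples), nrow = length(rows))
      z <- sqrt(intra_cor) * rep(f, each = length(rows)) +
        sqrt(1 - intra_cor) * eps
      x[rows, ] <- stats::pnorm(z)
    }
    list(x = x, module = module)
  })
}

#' Generate pathway gene sets around the planted structure
#'
#' Emits GMT-serializable gene sets over the cohort's gene universe. A
#' designated cancer-related subset of pathways draws the fraction
#' `overlap` of its genes from the planted genes of the cancer modules
#' (recorded in the ground truth); the remaining pathways are uniform draws
#' from the universe. With `overlap = 0` planted genes occur only at the
#' background rate.
#'
#' @param truth a `"ground_truth"` from [generate_cohort()].
#' @param n_pathways total number of pathways (0 gives an empty collection).
#' @param overlap fraction in \[0, 1\] of each cancer pathway drawn from
#'   cancer-module genes.
#' @param n_cancer number of cancer-related pathways (default ~30%).
#' @param size_range pathway sizes are drawn uniformly from this range.
#' @param seed integer seed.
#' @return A list of class `"pathway_collection"` with elements `pathways`
#'   (named list of gene vectors), `universe` and `cancer_related_ids`.
#' @export
generate_pathways <- function(truth, n_pathways = 20, overlap = 0.8,
                              n_cancer = max(1L, round(0.3 * n_pathways)),
                              size_range = c(10L, 20L), seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (overlap < 0 || overlap > 1) stop("`overlap` must lie in [0, 1]", call. = FALSE)
  universe <- truth$gene_universe
  cancer_pool <- names(truth$planted_module_of_gene)[
    truth$planted_module_of_gene %in% truth$cancer_module_ids]
  if (n_pathways == 0) {
    return(pathway_collection(list(), universe))
  }
  with_local_seed(seed, {
    n_cancer <- min(n_cancer, n_pathways)
    sets <- vector("list", n_pathways)
    names(sets) <- c(sprintf("CANCER_PW_%02d", seq_len(n_cancer)),
                     sprintf("PW_%02d", seq_len(n_pathways - n_cancer) +
                               n_cancer))[seq_len(n_pathways)]
    for (i in seq_len(n_pathways)) {
      size <- sample(size_range[1]:size_range[2], 1)
      if (i <= n_cancer) {
        n_hit <- round(overlap * size)
        if (n_hit > length(cancer_pool)) {
          stop("`overlap` requires more cancer-module genes than exist",
               call. = FALSE)
        }
        hit <- sample(cancer_pool, n_hit)
        rest <- sample(setdiff(universe, hit), size - n_hit)
        sets[[i]] <- sort(c(hit, rest))
      } else {
        sets[[i]] <- sort(sample(universe, size))
      }
    }
    pathway_collection(sets, universe,
                       cancer_related_ids = names(sets)[seq_len(n_cancer)])
  })
}

#' Generate labeled single cells from the true signature
#'
#' Cell expression is drawn as gamma noise around the cell type's signature
#' column (mean equal to the column, coefficient of variation
#' `dispersion`); every cell carries its true type label, standing in for
#' an annotated single-cell experiment.
#'
#' @param truth a `"ground_truth"` with at least two cell types.
#' @param cells_per_type cells per type (at least 2).
#' @param dispersion coefficient of variation of the per-gene gamma noise;
#'   0 gives exactly the signature column.
#' @param seed integer seed.
#' @return A list with `expr` (gene x cell matrix) and `labels` (named
#'   vector cell -> type).
#' @export
generate_single_cell <- function(truth, cells_per_type = 50, dispersion = 0.3,
                                 seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  sig <- truth$true_signature
  if (ncol(sig) < 2) stop("ground truth must carry at least 2 cell types", call. = FALSE)
  stopifnot_scalar_count(cells_per_type, "cells_per_type")
  if (cells_per_type < 2) {
    stop("`cells_per_type` must be at least 2 (marker testing needs replicates)",
         call. = FALSE)
  }
  with_local_seed(seed, {
    types <- colnames(sig)
    n_cells <- cells_per_type * length(types)
    expr <- matrix(0, nrow = nrow(sig), ncol = n_cells,
                   dimnames = list(rownames(sig), NULL))
    labels <- character(n_cells)
    cell_ids <- character(n_cells)
    j <- 0L
    for (t in types) {
      mu <- sig[, t]
      for (c in seq_len(cells_per_type)) {
        j <- j + 1L
        if (dispersion < 1e-8) {
          expr[, j] <- mu
        } else {
          shape <- 1 / dispersion^2
          expr[, j] <- rgamma(length(mu), shape = shape, scale = mu / shape)
        }
        labels[j] <- t
        cell_ids[j] <- sprintf("%s.%03d", t, c)
      }
    }
    colnames(expr) <- cell_ids
    names(labels) <- cell_ids
    list(expr = expr, labels = labels)
  })
}

#' Generate bulk expression as noisy cell-type mixtures
#'
#' `bulk = signature %*% t(proportions)` plus Gaussian noise, clipped at
#' zero. The reserved genes `GZMA` and `PRF1` sit in the signature's
#' T-cell column, so cytolytic activity scales with the planted cytotoxic
#' fraction.
#'
#' @param truth a `"ground_truth"`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @return A gene x sample expression matrix (columns are tumor samples).
#' @export
generate_bulk_expression <- function(truth, noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  sig <- truth$true_signature
  props <- truth$true_proportions
  stopifnot(identical(colnames(sig), colnames(props)))
  with_local_seed(seed, {
    bulk <- sig %*% t(props)
    if (noise_sd > 0) {
      bulk <- bulk + matrix(rnorm(length(bulk), 0, noise_sd), nrow = nrow(bulk))
    }
    bulk[bulk < 0] <- 0
    dimnames(bulk) <- list(rownames(sig), rownames(props))
    bulk
  })
}

#' Generate subgroup-dependent survival and clinical stage
#'
#' Event times are exponential with a per-subgroup hazard; censoring is an
#' independent exponential calibrated so that roughly `censor_rate` of
#' samples are censored (`censor_rate = 0` observes every event).
#' Categorical T/N/M stage columns and a tumor-infiltrating-lymphocyte
#' (TILs) pattern column are drawn from subgroup-dependent multinomials.
#'
#' @param truth a `"ground_truth"`.
#' @param hazard_by_subgroup named positive vector, one hazard (events per
#'   day) per subgroup label; defaults to a doubling hazard across
#'   subgroups starting at `log(2)/1000`.
#' @param censor_rate expected fraction censored, in \[0, 1).
#' @param seed integer seed.
#' @return A `data.frame` with `sample_id`, `subgroup`, `time` (days),
#'   `event` (0/1), `stage_T`, `stage_N`, `stage_M`, `tils_type`.
#' @export
generate_survival <- function(truth, hazard_by_subgroup = NULL,
                              censor_rate = 0.2, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  sg <- truth$subgroup_of_sample
  labs <- sort(unique(sg))
  if (is.null(hazard_by_subgroup)) {
    hazard_by_subgroup <- stats::setNames(
      log(2) / 1000 * 2^(seq_along(labs) - 1), labs)
  }
  if (any(hazard_by_subgroup <= 0)) stop("hazards must be positive", call. = FALSE)
  if (!all(labs %in% names(hazard_by_subgroup))) {
    stop("`hazard_by_subgroup` must name every subgroup", call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("`censor_rate` must lie in [0, 1)", call. = FALSE)
  }
  with_local_seed(seed, {
    n <- length(sg)
    lam <- hazard_by_subgroup[sg]
    t_event <- rexp(n, rate = lam)
    if (censor_rate > 0) {
      mu <- lam * censor_rate / (1 - censor_rate)
      t_cens <- rexp(n, rate = mu)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    # stage multinomials drift toward higher stage in later subgroups
    g <- match(sg, labs) - 1L
    draw_cat <- function(levels, base, slope) {
      vapply(g, function(gi) {
        p <- base + slope * gi
        p <- pmax(p, 0.02)
        sample(levels, 1, prob = p / sum(p))
      }, character(1))
    }
    stage_T <- draw_cat(paste0("T", 1:4), c(0.45, 0.3, 0.15, 0.1),
                        c(-0.12, -0.03, 0.07, 0.08))
    stage_N <- draw_cat(paste0("N", 0:2), c(0.6, 0.3, 0.1), c(-0.15, 0.08, 0.07))
    stage_M <- draw_cat(paste0("M", 0:1), c(0.9, 0.1), c(-0.08, 0.08))
    tils_levels <- c("brisk band-like", "brisk diffuse", "non-brisk focal",
                     "non-brisk multifocal")
    tils_type <- draw_cat(tils_levels, c(0.2, 0.35, 0.2, 0.25),
                          c(0.05, -0.15, 0.12, -0.02))
    data.frame(
      sample_id = names(sg), subgroup = unname(sg),
      time = time, event = event,
      stage_T = stage_T, stage_N = stage_N, stage_M = stage_M,
      tils_type = tils_type, stringsAsFactors = FALSE
    )
  })
}
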