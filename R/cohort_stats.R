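# Subgroup comparisons: Kaplan-Meier curves, log-rank tests, Pearson
# chi-square on clinical stage / TILs tables, Kruskal-Wallis on numeric
# features, and a per-subgroup summary report.

# Align a subgroup label vector with a clinical table's sample ids.
align_groups <- function(clinical, group) {
  if (inherits(group, "subgroup_assignment")) group <- group$subgroup
  g <- group[clinical$sample_id]
  orphans <- clinical$sample_id[is.na(g)]
  if (length(orphans) > 0) {
    stop("samples without subgroup label: ",
         paste(head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  unname(g)
}

#' Kaplan-Meier curves per subgroup
#'
#' Product-limit estimates per subgroup via [survival::survfit()].
#'
#' @param clinical data frame with `sample_id`, `time`, `event` (0/1).
#' @param group a `"subgroup_assignment"` or named sample -> label vector.
#' @return A `data.frame` with `group`, `time`, `n_risk`, `n_event`,
#'   `surv` (one row per distinct event/censoring time per group).
#' @export
km_curve <- function(clinical, group) {
  g <- align_groups(clinical, group)
  if (sum(clinical$event) < 1) {
    # still a valid (flat) estimate, returned without complaint
  }
  if (any(table(g) == 0)) stop("empty subgroup", call. = FALSE)
  fit <- survival::survfit(survival::Surv(clinical$time, clinical$event) ~ g)
  if (is.null(fit$strata)) {
    grp <- rep(unique(g), length(fit$time))
  } else {
    grp <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Log-rank test across subgroups
#'
#' Standard log-rank statistic ([survival::survdiff()]) referred to a
#' chi-square with `g - 1` degrees of freedom; handles more than two
#' groups.
#'
#' @inheritParams km_curve
#' @return A list: `chi2`, `df`, `p`.
#' @export
logrank <- function(clinical, group) {
  g <- align_groups(clinical, group)
  if (length(unique(g)) < 2) stop("need at least 2 subgroups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(clinical$time, clinical$event) ~ g)
  df <- length(sd$n) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Pearson chi-square on a contingency table
#'
#' Without continuity correction; all-zero rows or columns are dropped
#' with a warning before testing.
#'
#' @param contingency an r x c matrix or table of counts.
#' @return A list: `chi2`, `df`, `p`.
#' @export
chi_square <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(m) == 0) stop("empty table", call. = FALSE)
  zr <- rowSums(m) == 0; zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero row(s)/column(s) before testing")
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) stop("need a table of at least 2 x 2", call. = FALSE)
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Kruskal-Wallis comparison of a numeric feature across subgroups
#'
#' Rank-based H statistic with tie correction (via
#' [stats::kruskal.test()]); identical values across all samples give
#' `H = 0, p = 1` rather than an error.
#'
#' @param values named per-sample numeric vector, or unnamed and aligned
#'   with `group`.
#' @param group a `"subgroup_assignment"` or sample -> label vector.
#' @return A list: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, group) {
  if (inherits(group, "subgroup_assignment")) group <- group$subgroup
  if (!is.null(names(values)) && !is.null(names(group))) {
    group <- group[names(values)]
  }
  g <- factor(group)
  if (nlevels(g) < 2) stop("need at least 2 subgroups", call. = FALSE)
  if (any(table(g) < 2)) stop("need at least 2 samples per subgroup", call. = FALSE)
  if (length(unique(values)) == 1) {
    return(list(H = 0, df = nlevels(g) - 1, p = 1))
  }
  kt <- kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Per-subgroup summary report
#'
#' Tabulates, per subgroup: size, stage and TILs-type proportions, median
#' cytolytic activity, mean deconvolved cell-type proportions, and median
#' expression of checkpoint genes (PD-1 / PD-L1 symbols `PDCD1` and
#' `CD274` by default). Only the artifacts supplied are summarized.
#'
#' @param group a `"subgroup_assignment"` or sample -> label vector.
#' @param clinical optional clinical table (`sample_id`, stage columns,
#'   `tils_type`).
#' @param cyt optional named per-sample cytolytic activity.
#' @param proportions optional `"proportion_matrix"` or sample x type
#'   matrix.
#' @param bulk optional gene x sample expression for checkpoint medians.
#' @param checkpoint_genes checkpoint gene symbols to summarize.
#' @return A list of class `"subgroup_summary"`: `sizes`, `stage_props`,
#'   `tils_props`, `median_cyt`, `mean_proportions`,
#'   `checkpoint_medians` (absent blocks are `NULL`).
#' @export
summarize_subgroups <- function(group, clinical = NULL, cyt = NULL,
                                proportions = NULL, bulk = NULL,
                                checkpoint_genes = c("PDCD1", "CD274")) {
  if (inherits(group, "subgroup_assignment")) group <- group$subgroup
  labs <- sort(unique(group))
  if (any(table(group) == 0)) stop("empty subgroup", call. = FALSE)
  check_ids <- function(ids, what) {
    orphans <- setdiff(ids, names(group))
    if (length(orphans) > 0) {
      stop(sprintf("%s sample(s) without subgroup label: %s", what,
                   paste(head(orphans, 5), collapse = ", ")), call. = FALSE)
    }
  }
  out <- list(sizes = table(group))
  if (!is.null(clinical)) {
    check_ids(clinical$sample_id, "clinical")
    g <- group[clinical$sample_id]
    cat_props <- function(col) {
      if (is.null(clinical[[col]])) return(NULL)
      tab <- table(g, clinical[[col]])
      prop.table(tab, margin = 1)
    }
    out$stage_props <- Filter(Negate(is.null), list(
      stage_T = cat_props("stage_T"), stage_N = cat_props("stage_N"),
      stage_M = cat_props("stage_M")))
    out$tils_props <- cat_props("tils_type")
  }
  if (!is.null(cyt)) {
    check_ids(names(cyt), "CYT")
    out$median_cyt <- vapply(labs, function(l) {
      median(cyt[names(group)[group == l]], na.rm = TRUE)
    }, numeric(1))
    names(out$median_cyt) <- labs
  }
  if (!is.null(proportions)) {
    if (inherits(proportions, "proportion_matrix")) {
      proportions <- proportions$proportions
    }
    check_ids(rownames(proportions), "proportion")
    g <- group[rownames(proportions)]
    out$mean_proportions <- do.call(rbind, lapply(labs, function(l) {
      colMeans(proportions[g == l, , drop = FALSE])
    }))
    rownames(out$mean_proportions) <- labs
  }
  if (!is.null(bulk)) {
    genes <- intersect(checkpoint_genes, rownames(bulk))
    if (length(genes) > 0) {
      check_ids(colnames(bulk), "expression")
      g <- group[colnames(bulk)]
      out$checkpoint_medians <- do.call(rbind, lapply(labs, function(l) {
        apply(bulk[genes, g == l, drop = FALSE], 1, median)
      }))
      rownames(out$checkpoint_medians) <- labs
    }
  }
  structure(out, class = "subgroup_summary")
}

#' @export
print.subgroup_summary <- function(x, ...) {
  cat("Subgroup sizes:\n"); print(x$sizes)
  if (!is.null(x$median_cyt)) {
    cat("Median cytolytic activity:\n"); print(round(x$median_cyt, 3))
  }
  if (!is.null(x$mean_proportions)) {
    cat("Mean cell-type proportions:\n"); print(round(x$mean_proportions, 3))
  }
  invisible(x)
}
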