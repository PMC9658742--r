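# Feature selection and classification: stratified 7:3 split, greedy
# collinearity pruning, a shadow-feature (Boruta-style) random-forest
# selector, and a linear SVM evaluated by stratified cross-validated and
# held-out AUC.

#' Stratified train / held-out split
#'
#' Splits samples into a training fraction `ratio` and a held-out rest,
#' stratified by class so each class contributes its share to within one
#' sample of `ratio` (per-class training size is `round(ratio * n_class)`).
#'
#' @param labels named vector of class labels (names are sample ids).
#' @param ratio training fraction.
#' @param seed integer seed.
#' @return A list of class `"split_plan"`: `train_ids`, `heldout_ids`,
#'   `ratio`, `seed`.
#' @export
make_split <- function(labels, ratio = 0.7, seed = 1) {
  if (is.null(names(labels))) stop("`labels` must be named by sample id", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(tab < 2)) {
    stop("class with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  with_local_seed(seed, {
    train <- unlist(lapply(names(tab), function(cl) {
      ids <- names(labels)[labels == cl]
      sample(ids, round(ratio * length(ids)))
    }))
    structure(list(train_ids = sort(train),
                   heldout_ids = sort(setdiff(names(labels), train)),
                   ratio = ratio, seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' Greedy collinearity pruning
#'
#' Orders features by decreasing variance and keeps a feature only if its
#' absolute Pearson correlation with every already-kept feature is at most
#' `r_max`. Deterministic; a duplicated feature row survives exactly once.
#'
#' @param x feature x sample matrix.
#' @param r_max correlation threshold.
#' @return Character vector of kept feature ids (original matrix order).
#' @export
prune_collinear <- function(x, r_max = 0.9) {
  if (nrow(x) < 2) stop("need at least 2 features", call. = FALSE)
  feats <- rownames(x) %||% paste0("f", seq_len(nrow(x)))
  vars <- apply(x, 1, var)
  ord <- order(-vars, seq_along(vars))
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0) {
      kept <- i
      next
    }
    r <- suppressWarnings(abs(cor(x[i, ], t(x[kept, , drop = FALSE]))))
    r[is.na(r)] <- 0  # zero-variance feature correlates with nothing
    if (all(r <= r_max)) kept <- c(kept, i)
  }
  feats[sort(kept)]
}

#' Shadow-feature (Boruta-style) all-relevant feature selection
#'
#' Iteratively fits a random forest on the surviving (non-rejected)
#' features plus a column-permuted "shadow" copy of every input feature,
#' and counts a hit for each undecided feature whose importance (mean
#' decrease in impurity by default, permutation importance with
#' `importance = "permutation"`) exceeds the maximum shadow importance.
#' The shadow pool deliberately keeps its full size even after features
#' are rejected: a shrinking pool would weaken the null reference over
#' iterations and let spuriously label-correlated noise through. After each iteration a two-sided binomial
#' test of the hit count against p = 0.5, Bonferroni-corrected by the
#' number of input features, confirms features in the upper tail and
#' rejects them in the lower tail; undecided features after `max_iter`
#' iterations are tentative. Features are processed in name order, so the
#' decision sets are invariant to the input column order.
#'
#' @param x sample x feature matrix with unique column names, no missing
#'   values.
#' @param y two-class factor (or coercible) response.
#' @param n_trees random forest size per iteration.
#' @param mtry variables tried per split; the default (5% of the shadow-
#'   augmented column count, at least 2) is deliberately small so that
#'   importance spreads across correlated relevant features instead of
#'   concentrating on one representative.
#' @param alpha decision significance level (Bonferroni-corrected).
#' @param n_shadows independent shadow permutations per input feature.
#'   More shadows make the hit criterion (beating the maximum shadow)
#'   strictly harder, which keeps features that are only
#'   chance-correlated with the labels from accumulating hits.
#' @param max_iter maximum iterations; 0 leaves everything tentative.
#' @param importance `"impurity"` or `"permutation"`.
#' @param seed integer seed.
#' @return A list of class `"boruta_result"`: `confirmed`, `tentative`,
#'   `rejected` (character vectors partitioning the features),
#'   `n_iterations`, `hit_history` (feature x iteration 0/1 matrix).
#' @export
boruta_select <- function(x, y, n_trees = 500, mtry = NULL, alpha = 0.05,
                          n_shadows = 3, max_iter = 100,
                          importance = c("impurity", "permutation"), seed = 1) {
  importance <- match.arg(importance)
  x <- as.matrix(x)
  if (anyNA(x)) stop("`x` must not contain missing values", call. = FALSE)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)) > 0) {
    stop("`x` must have unique column names", call. = FALSE)
  }
  y <- factor(y)
  if (nlevels(y) < 2) stop("`y` must have at least 2 classes", call. = FALSE)
  # canonical feature order makes the result order-invariant
  x <- x[, order(colnames(x)), drop = FALSE]
  feats <- colnames(x)
  p <- length(feats)

  status <- stats::setNames(rep("tentative", p), feats)
  hits <- stats::setNames(rep(0L, p), feats)
  trials <- stats::setNames(rep(0L, p), feats)
  hit_history <- matrix(NA, nrow = p, ncol = 0, dimnames = list(feats, NULL))

  with_local_seed(seed, {
    iter <- 0L
    while (iter < max_iter && any(status == "tentative")) {
      iter <- iter + 1L
      surviving <- feats[status != "rejected"]
      xs <- x[, surviving, drop = FALSE]
      shadow <- do.call(cbind, lapply(seq_len(n_shadows), function(r) {
        sh <- apply(x, 2, sample)
        colnames(sh) <- paste0("shadow", r, "_", feats)
        sh
      }))
      dat <- cbind(xs, shadow)
      mtry_it <- if (is.null(mtry)) max(2, floor(0.05 * ncol(dat))) else mtry
      rf <- randomForest::randomForest(
        dat, y, ntree = n_trees, mtry = mtry_it,
        importance = (importance == "permutation")
      )
      imp <- randomForest::importance(
        rf, type = if (importance == "permutation") 1 else 2
      )[, 1]
      shadow_max <- max(imp[colnames(shadow)])
      undecided <- feats[status == "tentative"]
      hit <- imp[undecided] > shadow_max
      hits[undecided] <- hits[undecided] + as.integer(hit)
      trials[undecided] <- trials[undecided] + 1L
      hit_history <- cbind(hit_history, NA)
      hit_history[undecided, iter] <- as.integer(hit)

      # two-sided binomial decision, Bonferroni over features and looks
      n_corr <- p * max(max_iter, 1)
      for (f in undecided) {
        n <- trials[f]; h <- hits[f]
        p_two <- 2 * min(pbinom(h, n, 0.5), pbinom(h - 1, n, 0.5, lower.tail = FALSE))
        p_two <- min(p_two, 1)
        if (p_two * n_corr < alpha) {
          status[f] <- if (h > n / 2) "confirmed" else "rejected"
        }
      }
    }
    structure(
      list(confirmed = feats[status == "confirmed"],
           tentative = feats[status == "tentative"],
           rejected = feats[status == "rejected"],
           n_iterations = iter,
           hit_history = hit_history),
      class = "boruta_result"
    )
  })
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("Shadow-feature selection: %d confirmed, %d tentative, %d rejected (%d iterations)\n",
              length(x$confirmed), length(x$tentative), length(x$rejected),
              x$n_iterations))
  invisible(x)
}

#' Rank-based AUC
#'
#' Mann-Whitney AUC: the probability that a random positive outscores a
#' random negative, with ties contributing 1/2. Equals the area under the
#' ROC curve by trapezoidal integration.
#'
#' @param scores numeric scores (larger favors the positive class).
#' @param labels two-class labels; `positive` names the positive class
#'   (default: the last factor level).
#' @param positive positive class label.
#' @return A single number in \[0, 1\].
#' @export
compute_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("`labels` must have exactly 2 classes", call. = FALSE)
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: each class is dealt round-robin into k folds
# after a seeded shuffle.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Train and evaluate a linear SVM on selected features
#'
#' Standardizes the selected features, estimates a stratified
#' `k_folds`-fold cross-validated AUC on the training samples, refits on
#' the full training set, and reports the held-out AUC (plus the training
#' resubstitution AUC). Folds in which a class would vanish trigger a
#' reduction of `k_folds` with a warning.
#'
#' @param x sample x feature matrix.
#' @param y two-class response, named by sample id.
#' @param features feature subset to use (must exist in `x`).
#' @param plan a [make_split()] plan.
#' @param k_folds cross-validation folds.
#' @param cost SVM cost parameter.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param seed integer seed (fold assignment).
#' @return A list of class `"classifier_eval"`: `auc_train`, `auc_cv`,
#'   `auc_heldout`, `model` (the refit SVM), `kernel`, `cost`, `features`.
#' @export
train_eval <- function(x, y, features = colnames(x), plan, k_folds = 10,
                       cost = 1, kernel = c("linear", "radial"), seed = 1) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(plan, "split_plan"))
  missing_f <- setdiff(features, colnames(x))
  if (length(missing_f) > 0) {
    stop("features absent from the matrix: ",
         paste(head(missing_f, 5), collapse = ", "), call. = FALSE)
  }
  y <- factor(y)
  positive <- levels(y)[2]
  xt <- x[plan$train_ids, features, drop = FALSE]
  yt <- y[plan$train_ids]
  xh <- x[plan$heldout_ids, features, drop = FALSE]
  yh <- y[plan$heldout_ids]

  svm_scores <- function(fit, newx) {
    pr <- predict(fit, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient decision values toward the positive class
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    if (identical(first, positive)) dv[, 1] else -dv[, 1]
  }

  with_local_seed(seed, {
    k_eff <- min(k_folds, min(table(yt)))
    if (k_eff < k_folds) {
      warning(sprintf("reducing folds from %d to %d (smallest class size)",
                      k_folds, k_eff))
    }
    fold <- stratified_folds(yt, k_eff)
    cv_scores <- numeric(length(yt))
    for (f in seq_len(k_eff)) {
      in_f <- fold == f
      fit_f <- e1071::svm(xt[!in_f, , drop = FALSE], yt[!in_f],
                          kernel = kernel, cost = cost, scale = TRUE)
      cv_scores[in_f] <- svm_scores(fit_f, xt[in_f, , drop = FALSE])
    }
    auc_cv <- compute_auc(cv_scores, yt, positive)
    fit <- e1071::svm(xt, yt, kernel = kernel, cost = cost, scale = TRUE)
    auc_train <- compute_auc(svm_scores(fit, xt), yt, positive)
    auc_heldout <- compute_auc(svm_scores(fit, xh), yh, positive)
    structure(
      list(auc_train = auc_train, auc_cv = auc_cv, auc_heldout = auc_heldout,
           model = fit, kernel = kernel, cost = cost, features = features,
           positive = positive),
      class = "classifier_eval"
    )
  })
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("%s SVM (cost = %g) on %d features\n", x$kernel, x$cost,
              length(x$features)))
  cat(sprintf("  AUC  train: %.3f   cv: %.3f   held-out: %.3f\n",
              x$auc_train, x$auc_cv, x$auc_heldout))
  invisible(x)
}
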