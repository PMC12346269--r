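#' Configuration for the group pattern classifier
#'
#' The classifier is a radial-basis-function kernel method (kernel
#' ridge classification, the least-squares formulation of the SVM)
#' with two hyperparameters tuned on a log-spaced grid: regularization
#' strength `lambda` and kernel scale (a multiplier of the median
#' pairwise distance in the training features). Dimensionality is
#' reduced by PCA to the top components explaining
#' `variance_threshold` of the variance; `pca_scope = "per_fold"`
#' (default) refits the PCA on each training fold to avoid leakage,
#' `"whole_subsample"` mirrors the original order of operations
#' (reduction before cross-validation).
#'
#' @param lambda_grid regularization strengths.
#' @param scale_grid kernel-scale multipliers of the median pairwise
#'   distance.
#' @param variance_threshold cumulative explained-variance cutoff.
#' @param n_subsamples balanced subsampling repeats.
#' @param n_label_perms label permutations for the significance test.
#' @param n_perm_subsamples subsample repeats per label permutation.
#' @param pca_scope `"per_fold"` or `"whole_subsample"`.
#' @param seed integer seed.
#' @export
classifier_config <- function(lambda_grid = 10^seq(-3, 1, length.out = 5),
                              scale_grid = 2^seq(-2, 2, length.out = 5),
                              variance_threshold = 0.95,
                              n_subsamples = 200L,
                              n_label_perms = 500L,
                              n_perm_subsamples = 1L,
                              pca_scope = c("per_fold", "whole_subsample"),
                              seed = 1L) {
  if (!length(lambda_grid) || !length(scale_grid))
    stop_invalid("hyperparameter grid must be non-empty")
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop_invalid("variance_threshold must be in (0, 1]")
  list(lambda_grid = lambda_grid, scale_grid = scale_grid,
       variance_threshold = variance_threshold,
       n_subsamples = as.integer(n_subsamples),
       n_label_perms = as.integer(n_label_perms),
       n_perm_subsamples = as.integer(n_perm_subsamples),
       pca_scope = match.arg(pca_scope), seed = as.integer(seed))
}

#' Balance two classes by subsampling the larger group
#'
#' @param features samples x features matrix.
#' @param labels two-level factor/vector.
#' @param seed integer seed.
#' @return list(features, labels, index) with equal class counts; the
#'   index is relative to the input rows, without duplicates.
#' @export
balance_subsample <- function(features, labels, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop_invalid("need exactly two classes")
  labels <- droplevels(labels)
  tab <- table(labels)
  if (tab[1] == tab[2]) {
    idx <- seq_along(labels)
  } else {
    small <- names(tab)[which.min(tab)]
    large <- names(tab)[which.max(tab)]
    idx_small <- which(labels == small)
    idx_large <- which(labels == large)
    keep_large <- with_seed(seed,
                            sort(sample(idx_large, length(idx_small))))
    idx <- sort(c(idx_small, keep_large))
  }
  list(features = as.matrix(features)[idx, , drop = FALSE],
       labels = labels[idx], index = idx)
}

#' PCA dimensionality reduction to a variance threshold
#'
#' Keeps the smallest number of leading principal components whose
#' cumulative explained variance reaches `variance_threshold`.
#' Zero-variance features are dropped with a warning. When
#' `train_index` is given the transform is fitted on those rows only
#' and applied to all rows (the per-fold scope).
#'
#' @param features samples x features matrix.
#' @param variance_threshold cumulative explained-variance cutoff.
#' @param train_index optional rows to fit the transform on.
#' @return list(scores, rotation, center, n_components, explained).
#' @export
reduce_dimensionality <- function(features, variance_threshold = 0.95,
                                  train_index = NULL) {
  X <- as.matrix(features)
  v <- apply(X, 2, var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance feature(s)",
            call. = FALSE)
    X <- X[, v > 0, drop = FALSE]
  }
  fit_rows <- train_index %||% seq_len(nrow(X))
  ctr <- colMeans(X[fit_rows, , drop = FALSE])
  Xc <- sweep(X[fit_rows, , drop = FALSE], 2, ctr)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2
  ev <- ev[ev > max(ev) * 1e-12]
  ncomp <- which(cumsum(ev) / sum(ev) >= variance_threshold)[1]
  rot <- sv$v[, seq_len(ncomp), drop = FALSE]
  list(scores = sweep(X, 2, ctr) %*% rot, rotation = rot, center = ctr,
       n_components = ncomp, explained = ev / sum(ev))
}

#' F1 score from a confusion matrix (counts)
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`; returns `NA` with a warning when
#' the denominator is zero.
#'
#' @param confusion list or vector with elements `TP`, `FP`, `FN`
#'   (and optionally `TN`).
#' @export
f1_from_confusion <- function(confusion) {
  cf <- as.list(confusion)
  den <- 2 * cf$TP + cf$FP + cf$FN
  if (den == 0) {
    warning("F1 undefined: 2TP + FP + FN = 0", call. = FALSE)
    return(NA_real_)
  }
  2 * cf$TP / den
}

# RBF kernel from squared distances
.rbf <- function(D2, scale) exp(-D2 / (2 * scale^2))

.sqdist <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  pmax(outer(an, bn, `+`) - 2 * tcrossprod(A, B), 0)
}

# Closed-form LOO scores for kernel ridge: with H = K (K + lambda I)^-1,
# loo_i = (yhat_i - H_ii y_i) / (1 - H_ii).
.krr_loo_scores <- function(K, y, lambda) {
  n <- nrow(K)
  Ainv <- solve(K + diag(lambda, n))
  H <- K %*% Ainv
  yhat <- H %*% y
  h <- diag(H)
  as.numeric((yhat - h * y) / (1 - h))
}

# ROC-AUC via the rank formula (equivalent to pair counting with ties
# counted 1/2).
.roc_auc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# One balanced subsample: LOO predictions + continuous scores.
.loocv_subsample <- function(X, y01, config) {
  n <- nrow(X)
  yy <- ifelse(y01, 1, -1)
  grid <- expand.grid(lambda = config$lambda_grid,
                      scale_mult = config$scale_grid)
  if (config$pca_scope == "whole_subsample") {
    red <- reduce_dimensionality(X, config$variance_threshold)
    Z <- red$scores
    D2 <- .sqdist(Z)
    s0 <- sqrt(median(D2[upper.tri(D2)]))
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      K <- .rbf(D2, s0 * grid$scale_mult[g])
      sc <- .krr_loo_scores(K, yy, grid$lambda[g])
      acc <- mean((sc > 0) == y01)
      if (is.null(best) || acc > best$acc) best <- list(acc = acc, sc = sc)
    }
    return(list(scores = best$sc, truth = y01))
  }
  # per-fold: PCA and hyperparameter selection on the training fold only
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    red <- reduce_dimensionality(X, config$variance_threshold,
                                 train_index = tr)
    Ztr <- red$scores[tr, , drop = FALSE]
    Zte <- red$scores[i, , drop = FALSE]
    D2 <- .sqdist(Ztr)
    s0 <- sqrt(median(D2[upper.tri(D2)]))
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      K <- .rbf(D2, s0 * grid$scale_mult[g])
      sc <- .krr_loo_scores(K, yy[tr], grid$lambda[g])
      acc <- mean((sc > 0) == y01[tr])
      if (is.null(best) || acc > best$acc)
        best <- list(acc = acc, lambda = grid$lambda[g],
                     scale = s0 * grid$scale_mult[g])
    }
    K <- .rbf(D2, best$scale)
    alpha <- solve(K + diag(best$lambda, n - 1L), yy[tr])
    kte <- .rbf(.sqdist(Zte, Ztr), best$scale)
    scores[i] <- as.numeric(kte %*% alpha)
  }
  list(scores = scores, truth = y01)
}

#' Train and evaluate the group classifier with LOO cross-validation
#'
#' Repeats `n_subsamples` times: balance classes by subsampling the
#' larger group, reduce dimensionality by PCA, tune the two kernel
#' hyperparameters by (inner) leave-one-out accuracy, and collect
#' leave-one-out predictions and continuous scores. Reports the mean
#' accuracy across subsamples, the aggregated confusion matrix, the F1
#' score, and the ROC-AUC with its 66% percentile confidence interval
#' (17th-83rd percentiles across subsamples).
#'
#' @param features samples x features matrix.
#' @param labels two-level factor; the *second* level is the positive
#'   class (override with `positive_class`).
#' @param config a [classifier_config()].
#' @param positive_class label treated as positive.
#' @return `classification_report`: list(mean_accuracy, confusion, f1,
#'   roc_auc, roc_auc_ci, p_value = NA, per_subsample).
#' @export
train_eval_loocv <- function(features, labels, config = classifier_config(),
                             positive_class = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop_invalid("need exactly two classes")
  positive_class <- positive_class %||% levels(labels)[2]
  X <- as.matrix(features)
  recs <- vector("list", config$n_subsamples)
  for (s in seq_len(config$n_subsamples)) {
    bal <- balance_subsample(X, labels, seed = config$seed + 7919L * s)
    y01 <- bal$labels == positive_class
    out <- .loocv_subsample(bal$features, y01, config)
    pred <- out$scores > 0
    recs[[s]] <- data.frame(
      subsample = s,
      accuracy = mean(pred == y01),
      auc = .roc_auc(out$scores, y01),
      TP = sum(pred & y01), FP = sum(pred & !y01),
      FN = sum(!pred & y01), TN = sum(!pred & !y01))
  }
  per <- do.call(rbind, recs)
  confusion <- list(TP = sum(per$TP), FP = sum(per$FP),
                    FN = sum(per$FN), TN = sum(per$TN))
  structure(list(
    mean_accuracy = mean(per$accuracy),
    confusion = confusion,
    f1 = f1_from_confusion(confusion),
    roc_auc = mean(per$auc),
    roc_auc_ci = quantile(per$auc, c(0.17, 0.83), names = FALSE),
    p_value = NA_real_,
    positive_class = positive_class,
    per_subsample = per), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> accuracy = %.3f, F1 = %.3f, ",
                     "AUC = %.3f [%.3f, %.3f]%s\n"),
              x$mean_accuracy, x$f1, x$roc_auc,
              x$roc_auc_ci[1], x$roc_auc_ci[2],
              if (is.na(x$p_value)) ""
              else sprintf(", p = %s", format.pval(x$p_value))))
  invisible(x)
}

#' Label-permutation p-value for classification accuracy
#'
#' Shuffles the class labels `n_label_perms` times, re-runs the full
#' balanced-subsample LOO procedure (with `n_perm_subsamples` repeats
#' per shuffle, pooled into one null distribution of accuracies), and
#' returns `p = (1 + #{null >= observed}) / (1 + n_null)`.
#'
#' @inheritParams train_eval_loocv
#' @param observed_accuracy accuracy from the non-shuffled data.
#' @return list(p, null_accuracies).
#' @export
permutation_pvalue <- function(features, labels, config,
                               observed_accuracy,
                               positive_class = NULL) {
  labels <- droplevels(as.factor(labels))
  null_acc <- numeric(0)
  for (b in seq_len(config$n_label_perms)) {
    yp <- with_seed(config$seed + 104729L * b,
                    factor(sample(as.character(labels)),
                           levels = levels(labels)))
    cfg <- config
    cfg$n_subsamples <- config$n_perm_subsamples
    cfg$seed <- config$seed + 104729L * b
    rep_b <- train_eval_loocv(features, yp, cfg,
                              positive_class = positive_class)
    null_acc <- c(null_acc, rep_b$per_subsample$accuracy)
  }
  list(p = (1 + sum(null_acc >= observed_accuracy)) /
         (1 + length(null_acc)),
       null_accuracies = null_acc)
}

#' Classify groups and test significance in one call
#'
#' Convenience wrapper: [train_eval_loocv()] followed by
#' [permutation_pvalue()], returning the report with `p_value` filled.
#'
#' @inheritParams train_eval_loocv
#' @export
classify_groups <- function(features, labels,
                            config = classifier_config(),
                            positive_class = NULL) {
  rep0 <- train_eval_loocv(features, labels, config, positive_class)
  pp <- permutation_pvalue(features, labels, config, rep0$mean_accuracy,
                           positive_class)
  rep0$p_value <- pp$p
  rep0$null_accuracies <- pp$null_accuracies
  rep0
}
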