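test_that("balance_subsample equalizes classes without duplication", {
  X <- matrix(withr::with_seed(1, rnorm(77 * 3)), 77, 3)
  y <- factor(rep(c("HC", "FEP"), c(45, 32)))
  bal <- balance_subsample(X, y, seed = 4)
  expect_equal(as.numeric(table(bal$labels)), c(32, 32))
  expect_true(all(bal$index %in% seq_len(77)))
  expect_false(anyDuplicated(bal$index) > 0)
  # equal classes unchanged
  y2 <- factor(rep(c("a", "b"), each = 10))
  bal2 <- balance_subsample(X[1:20, ], y2, seed = 1)
  expect_identical(bal2$index, 1:20)
  expect_error(balance_subsample(X, factor(rep("a", 77))), "two classes")
})

test_that("reduce_dimensionality honors rank, threshold and scope", {
  # data in an exact 3-dimensional subspace: 3 components at any
  # threshold < 1
  B <- withr::with_seed(2, matrix(rnorm(3 * 30), 3, 30))
  S <- withr::with_seed(3, matrix(rnorm(40 * 3), 40, 3))
  red <- reduce_dimensionality(S %*% B, 0.95)
  expect_equal(red$n_components, 3L)

  # variance accounting: residual variance <= (1 - threshold) * total
  X <- withr::with_seed(4, matrix(rnorm(50 * 20), 50, 20))
  red2 <- reduce_dimensionality(X, 0.8)
  Xc <- sweep(X, 2, red2$center)
  recon <- red2$scores %*% t(red2$rotation)
  expect_lte(sum((Xc - recon)^2), (1 - 0.8) * sum(Xc^2) + 1e-8)

  # per-fold scope (train_index) produces a different transform
  red3 <- reduce_dimensionality(X, 0.8, train_index = 1:25)
  expect_false(isTRUE(all.equal(red2$rotation[, 1], red3$rotation[, 1])))

  Xz <- cbind(X, 0)
  expect_warning(reduce_dimensionality(Xz, 0.8), "zero-variance")
})

test_that("f1_from_confusion implements the count formula", {
  expect_equal(f1_from_confusion(list(TP = 5, FP = 0, FN = 0, TN = 3)), 1)
  expect_equal(f1_from_confusion(list(TP = 10, FP = 5, FN = 5, TN = 0)),
               20 / 30)
  expect_equal(f1_from_confusion(list(TP = 0, FP = 2, FN = 1, TN = 7)), 0)
  expect_warning(
    expect_true(is.na(f1_from_confusion(list(TP = 0, FP = 0, FN = 0,
                                             TN = 9)))),
    "undefined")
})

test_that("ROC-AUC equals exhaustive pair counting on small toys", {
  pair_auc <- function(scores, pos) {
    ps <- scores[pos]; ns <- scores[!pos]
    tot <- 0
    for (p in ps) for (q in ns)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(ps) * length(ns))
  }
  for (s in 1:25) {
    n <- withr::with_seed(s, sample(4:12, 1))
    scores <- withr::with_seed(s + 30, round(rnorm(n), 1))  # induce ties
    pos <- withr::with_seed(s + 60,
                            sample(c(TRUE, FALSE), n, replace = TRUE))
    if (!any(pos) || all(pos)) next
    expect_equal(cortexdyn:::.roc_auc(scores, pos),
                 pair_auc(scores, pos))
  }
})

test_that("train_eval_loocv separates well-separated clusters", {
  d <- withr::with_seed(7, list(
    X = rbind(matrix(rnorm(20 * 5), 20, 5),
              matrix(rnorm(20 * 5, mean = 10), 20, 5)),
    y = factor(rep(c("ctl", "pat"), each = 20))))
  cfg <- classifier_config(n_subsamples = 3, seed = 1)
  rep1 <- train_eval_loocv(d$X, d$y, cfg, positive_class = "pat")
  expect_gte(rep1$mean_accuracy, 0.95)
  expect_gte(rep1$roc_auc, 0.99)
  expect_equal(rep1$f1, 1, tolerance = 0.05)
  expect_true(all(rep1$roc_auc_ci >= 0 & rep1$roc_auc_ci <= 1))
  expect_error(train_eval_loocv(d$X, d$y,
                                classifier_config(lambda_grid = numeric(0))),
               "non-empty")
})

test_that("both PCA scopes run and chance data stays at chance", {
  d <- withr::with_seed(8, list(X = matrix(rnorm(30 * 40), 30, 40),
                                y = factor(rep(c("a", "b"), 15))))
  cfg_w <- classifier_config(n_subsamples = 2, seed = 2,
                             pca_scope = "whole_subsample")
  cfg_f <- classifier_config(n_subsamples = 2, seed = 2,
                             pca_scope = "per_fold")
  acc_w <- train_eval_loocv(d$X, d$y, cfg_w)$mean_accuracy
  acc_f <- train_eval_loocv(d$X, d$y, cfg_f)$mean_accuracy
  expect_between(acc_w, 0.1, 0.9)
  expect_between(acc_f, 0.1, 0.9)
})

test_that("permutation_pvalue is deterministic and extreme when separable", {
  d <- withr::with_seed(9, list(
    X = rbind(matrix(rnorm(12 * 4), 12, 4),
              matrix(rnorm(12 * 4, mean = 8), 12, 4)),
    y = factor(rep(c("a", "b"), each = 12))))
  cfg <- classifier_config(n_subsamples = 1, n_label_perms = 19,
                           n_perm_subsamples = 1, seed = 5,
                           pca_scope = "whole_subsample")
  obs <- train_eval_loocv(d$X, d$y, cfg)$mean_accuracy
  p1 <- permutation_pvalue(d$X, d$y, cfg, obs)
  p2 <- permutation_pvalue(d$X, d$y, cfg, obs)
  expect_identical(p1$p, p2$p)
  expect_equal(p1$p, 1 / 20)            # attainable minimum
})
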