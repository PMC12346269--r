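random_xy <- function(seed, n = 180, p = 6) {
  withr::with_seed(seed, list(X = matrix(rnorm(n * p), n, p),
                              Y = matrix(rnorm(n * p), n, p)))
}

# generalized-eigenvalue oracle for canonical correlations
cca_eigen_oracle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc); Syy <- crossprod(Yc); Sxy <- crossprod(Xc, Yc)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  sqrt(sort(pmax(Re(eigen(M, only.values = TRUE)$values), 0),
            decreasing = TRUE))
}

test_that("fit_cca matches the generalized-eigenvalue oracle", {
  for (s in 1:10) {
    d <- random_xy(s)
    res <- fit_cca(d$X, d$Y)
    expect_equal(res$correlations, cca_eigen_oracle(d$X, d$Y),
                 tolerance = 1e-6)
  }
})

test_that("fit_cca: self-correlation, invariance, orthogonality", {
  d <- random_xy(77)
  res <- fit_cca(d$X, d$X)
  expect_equal(res$correlations, rep(1, 6), tolerance = 1e-8)
  expect_equal(explained_covariance(res), rep(1 / 6, 6))

  # invertible column transform of X leaves all correlations at 1
  A <- matrix(c(2, 0.5, 0, 0, 0, 0,
                0, 3, 0, 0, 0, 0,
                0, 0, 1, 0.2, 0, 0,
                0, 0, 0, 2, 0, 0,
                0, 0, 0, 0, 5, 1,
                0, 0, 0, 0, 0, 0.5), 6, 6)
  res2 <- fit_cca(d$X, d$X[, c(3, 1, 2, 6, 5, 4)] %*% A)
  expect_equal(res2$correlations, rep(1, 6), tolerance = 1e-8)

  # canonical variables within a block mutually uncorrelated
  res3 <- fit_cca(d$X, d$Y)
  cz <- cor(res3$Zx)
  expect_lt(max(abs(cz[upper.tri(cz)])), 1e-6)
  # |corr(Zx_i, Zy_i)| equals R_i
  ci <- vapply(1:6, function(i) abs(cor(res3$Zx[, i], res3$Zy[, i])),
               numeric(1))
  expect_equal(ci, res3$correlations, tolerance = 1e-8)
  # descending order
  expect_true(all(diff(res3$correlations) <= 1e-12))

  # rank-deficient input names the offending columns
  Xbad <- d$X; Xbad[, 3] <- 2 * Xbad[, 1]
  expect_error(fit_cca(Xbad, d$Y), "rank-deficient X")
  # missing rows dropped listwise
  Xna <- d$X; Xna[c(5, 9), 2] <- NA
  resna <- fit_cca(Xna, d$Y)
  expect_equal(resna$n_dropped, 2L)
  expect_equal(length(resna$rows_used), 178L)
})

test_that("explained_covariance and loadings follow their formulas", {
  # rank-1 coupling: first fraction > 0.9. The residual canonical
  # correlations are pure sampling correlations of order sqrt(p/n)
  # whatever the noise amplitude (CCA is scale invariant), so the
  # dominance statement needs n >> p^2; tested at n = 800 rows.
  d <- random_xy(5, n = 800)
  w <- withr::with_seed(15, rnorm(6))
  Y <- d$X[, 1] %*% t(w) +
    0.05 * matrix(withr::with_seed(16, rnorm(800 * 6)), 800, 6)
  res <- fit_cca(d$X, Y)
  expect_gt(explained_covariance(res)[1], 0.9)
  expect_equal(sum(explained_covariance(res)), 1, tolerance = 1e-12)

  # loadings equal direct correlations with the first canonical variable
  ld <- cca_loadings(res, d$X, Y)
  oracle_x <- vapply(1:6, function(j) cor(d$X[, j], res$Zx[, 1]),
                     numeric(1))
  expect_equal(unname(ld$loadings_x), unname(oracle_x), tolerance = 1e-10)
  # sign convention: largest-magnitude X loading positive
  expect_gt(ld$loadings_x[which.max(abs(ld$loadings_x))], 0)

  # single-column blocks: loading = +/-1
  res1 <- fit_cca(d$X[, 1, drop = FALSE], Y[, 1, drop = FALSE])
  expect_equal(abs(res1$loadings_x), 1, tolerance = 1e-10)
})

test_that("cca_significance is extreme for coupled maps and shares rotations", {
  g <- small_geom(90, seed = 2)
  L <- smooth_map_factor(g, 0.3)
  X <- simulate_smooth_map(g, 0.3, seed = 3, n_maps = 6, factor = L)
  Y <- X[, c(1, 1, 2, 2, 3, 3)] +
    0.1 * matrix(withr::with_seed(4, rnorm(90 * 6)), 90, 6)
  rl <- spin_rotations(g, 199, seed = 5)
  res <- cca_significance(X, Y, rl)
  expect_equal(res$p_value, 1 / 200)      # minimum attainable
  expect_identical(res$statistic, "canonical_r")
})

test_that("cca_reproducibility cross-correlates canonical patterns", {
  g <- small_geom(90, seed = 6)
  L <- smooth_map_factor(g, 0.3)
  base <- simulate_smooth_map(g, 0.3, seed = 11, n_maps = 6, factor = L)
  w <- withr::with_seed(3, rnorm(6))
  mk <- function(seed) {
    N1 <- 0.3 * matrix(withr::with_seed(seed, rnorm(90 * 6)), 90, 6)
    N2 <- 0.3 * matrix(withr::with_seed(seed + 50, rnorm(90 * 6)), 90, 6)
    list(X = base + N1, Y = base[, 1] %*% t(w) + N2)
  }
  d1 <- mk(1); d2 <- mk(2)
  r1 <- fit_cca(d1$X, d1$Y); r2 <- fit_cca(d2$X, d2$Y)

  # identical fits: all cross-correlations 1
  same <- cca_reproducibility(list(r1, r1))
  expect_equal(same$zx_cross[1, 2], 1, tolerance = 1e-12)
  expect_equal(same$loadings_x_cross[1, 2], 1, tolerance = 1e-12)

  # split-half of a coupled design: X-side first variables reproducible
  # beyond an independent-maps null (95th percentile over 50 pairs)
  rep12 <- cca_reproducibility(list(r1, r2))
  null_cross <- vapply(1:50, function(s) {
    a <- simulate_smooth_map(g, 0.3, seed = 100 + s)
    b <- simulate_smooth_map(g, 0.3, seed = 600 + s)
    abs(spearman_map_corr(map_values(a), map_values(b)))
  }, numeric(1))
  expect_gt(abs(rep12$zx_cross[1, 2]), quantile(null_cross, 0.95))

  # loadings cross-correlation equals the small-n rank formula
  lx1 <- r1$loadings_x; lx2 <- r2$loadings_x
  oracle <- 1 - 6 * sum((rank(lx1) - rank(lx2))^2) / (6 * 35)
  expect_equal(rep12$loadings_x_cross[1, 2], oracle)
})
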