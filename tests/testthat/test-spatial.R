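test_that("spearman_map_corr matches the rank formula and handles NA", {
  a <- c(3, 1, 4, 1.5, 9)
  b <- c(2, 7, 1, 8, 3)
  # brute-force rank formula oracle (no ties here)
  ra <- rank(a); rb <- rank(b); n <- 5
  oracle <- 1 - 6 * sum((ra - rb)^2) / (n * (n^2 - 1))
  expect_equal(spearman_map_corr(a, b), oracle)
  expect_equal(spearman_map_corr(a, a), 1)
  expect_equal(spearman_map_corr(a, -a), -1)
  # invariance under strictly monotone transforms
  expect_equal(spearman_map_corr(exp(a), b^3), oracle)
  expect_error(spearman_map_corr(c(1, 2, NA, NA), c(1, NA, 2, 3)),
               "non-missing")
})

test_that("spin_rotations produces valid deterministic reassignments", {
  g <- make_geometry(60, seed = 3, n_medial = 5)
  expect_identical(spin_rotations(g, 20, seed = 4),
                   spin_rotations(g, 20, seed = 4))
  rl <- spin_rotations(g, 100, seed = 7)
  expect_equal(dim(rl), c(100L, 60L))
  # every source index valid and never a medial-wall parcel
  expect_true(all(rl >= 1 & rl <= 60))
  expect_false(any(g$medial_wall[as.integer(rl)]))
  # identity rotation: identity permutation on non-medial sources
  id <- spin_assign(g, diag(3))
  expect_identical(id[!g$medial_wall], which(!g$medial_wall))
})

test_that("spin_pvalue: extreme case, multiparameter sharing, skipping", {
  g <- small_geom(60, seed = 1)
  rl <- spin_rotations(g, 99, seed = 2)
  m <- map_values(simulate_smooth_map(g, 0.5, seed = 3))
  # map against itself: observed rho = 1 beats every null
  res <- spin_pvalue(spearman_map_corr, m, m, rl)
  expect_equal(res$p_value, 1 / 100)
  expect_equal(res$value, 1)

  # stacked parameters share one rotation per permutation: correlating
  # column differences is invariant when both columns rotate together
  M <- cbind(m, m)
  stat <- function(A, B) max(abs(A[, 1] - A[, 2]))
  res2 <- spin_pvalue(stat, M, NULL, rl)
  expect_true(all(abs(res2$null_values) < 1e-12))

  # statistic undefined on some rotations: skipped and counted
  # (observed overlap is exactly 3; many rotations map fewer than 3
  # non-missing sources onto the support)
  m_na <- m; m_na[4:60] <- NA
  res3 <- spin_pvalue(spearman_map_corr, m_na, m, rl)
  expect_gt(res3$n_skipped, 0)
})

test_that("axis_projection_fit selects linear and quadratic orders", {
  g <- small_geom(120, seed = 5)
  yz <- g$anat_xyz[, 2] + g$anat_xyz[, 3]
  x <- (yz - mean(yz)) / sd(yz)

  lin <- withr::with_seed(1, 2 * x + rnorm(120, 0, 0.01))
  f1 <- axis_projection_fit(lin, g, "y_plus_z")
  expect_equal(f1$order, 1L)
  expect_gt(f1$r_squared, 0.95)
  expect_lt(f1$p_value, 1e-6)

  quad <- withr::with_seed(2, x^2 - mean(x^2) + rnorm(120, 0, 0.01))
  f2 <- axis_projection_fit(quad, g, "y_plus_z")
  expect_equal(f2$order, 2L)

  # pure noise: order 1, R^2 near 0, nonsignificant in >= 90% of 20
  null_ok <- vapply(1:20, function(s) {
    fn <- axis_projection_fit(withr::with_seed(s + 10, rnorm(120)),
                              g, "x")
    fn$order == 1L && fn$r_squared < 0.1 && fn$p_value > 0.05
  }, logical(1))
  expect_gte(mean(null_ok), 0.9)

  degen <- parcel_geometry(1:3, diag(3), matrix(1, 3, 3))
  expect_error(axis_projection_fit(rnorm(3), degen, "x"), "degenerate")
})

test_that("morans_i matches closed forms on lattices and permutations", {
  # alternating +/-1 on a ring with 2-neighbour weights: I = -1 exactly
  n <- 40
  W <- ring_weights(n)
  alt <- rep(c(1, -1), n / 2)
  expect_equal(morans_i(alt, weights = W)$value, -1)

  # smooth gradient along y: positive autocorrelation
  g <- small_geom(80, seed = 4)
  grad <- g$anat_xyz[, 2]
  expect_gt(morans_i(grad, g)$value, 0)

  # random permutation: E[I] = -1/(N-1)
  m <- map_values(simulate_smooth_map(g, 0.5, seed = 6))
  perm_i <- withr::with_seed(8, vapply(1:100, function(b)
    morans_i(m[sample.int(80)], g)$value, numeric(1)))
  expect_equal(mean(perm_i), -1 / 79, tolerance = 0.02)

  expect_error(morans_i(rep(1, 40), weights = W), "zero variance")
})

test_that("bootstrap_ci: degenerate, coverage-consistent, deterministic", {
  expect_equal(as.numeric(bootstrap_ci(mean, rep(2.5, 10),
                                       n_boot = 200, seed = 1)),
               c(2.5, 2.5))
  x0 <- withr::with_seed(42, rnorm(50))
  expect_identical(
    as.numeric(bootstrap_ci(mean, x0, n_boot = 200, seed = 9)),
    as.numeric(bootstrap_ci(mean, x0, n_boot = 200, seed = 9)))
  # coverage: 95% interval for the mean of N(0,1), n=100, covers 0 in
  # about 95% of outer replicates (scaled down: 100 outer, 300 boot)
  cover <- vapply(1:100, function(r) {
    x <- withr::with_seed(r + 400, rnorm(100))
    ci <- bootstrap_ci(mean, x, n_boot = 300, seed = r)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_between(mean(cover), 0.88, 0.99)
  # statistic undefined on a resample: redrawn and logged
  flaky <- function(x) if (x[1] > 0) mean(x) else NA_real_
  ci <- bootstrap_ci(flaky, c(-1, 1, 2, 3), n_boot = 50, seed = 3)
  expect_true(attr(ci, "n_redrawn") >= 0)
  expect_error(bootstrap_ci(mean, 1), "sample size")
})
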