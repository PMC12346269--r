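#' Spearman correlation between two parcel maps
#'
#' Rank correlation (average-rank ties) over jointly non-missing
#' parcels. The workhorse statistic for comparing cortical maps.
#'
#' @param mapA,mapB numeric maps of equal length (NA allowed).
#' @param min_overlap minimum number of jointly non-missing parcels.
#' @export
spearman_map_corr <- function(mapA, mapB, min_overlap = 3L) {
  a <- as.numeric(mapA); b <- as.numeric(mapB)
  if (length(a) != length(b)) stop_invalid("map lengths differ")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_overlap)
    stop_invalid("fewer than ", min_overlap, " jointly non-missing parcels")
  cor(rank(a[ok]), rank(b[ok]))
}

#' Generate spin-rotation reassignments for a parcellation
#'
#' Applies `n_rotations` uniformly random 3D rotations (quaternion
#' sampling over SO(3)) to the parcel centroids on the sphere. After
#' each rotation, every original parcel is reassigned the value of the
#' parcel whose rotated centroid is closest; when the closest source is
#' a medial-wall parcel, the next closest non-medial parcel is used.
#' The resulting index log is reused across statistics (and across the
#' parameter maps of a multiparameter test) so that all maps share the
#' same rotation within one permutation.
#'
#' @param geometry a [parcel_geometry()].
#' @param n_rotations number of random rotations.
#' @param seed integer seed.
#' @return `spin_rotation_log`: an `n_rotations x n_parcels` integer
#'   matrix of source indices, with attributes `seed`, `n_parcels`.
#' @export
spin_rotations <- function(geometry, n_rotations, seed = 1L) {
  s <- geometry$sphere_xyz
  ok_source <- !geometry$medial_wall
  idx <- with_seed(seed, {
    t(vapply(seq_len(n_rotations), function(r) {
      R <- random_rotation_matrix()
      spin_assign(geometry, R, ok_source = ok_source, sphere = s)
    }, integer(nrow(s))))
  })
  structure(idx, class = "spin_rotation_log", seed = seed,
            n_parcels = nrow(s))
}

#' Reassignment induced by a single rotation matrix
#'
#' Exposed for testing: the identity rotation yields the identity
#' permutation (up to medial-wall exclusions).
#'
#' @param geometry a [parcel_geometry()].
#' @param rotation 3 x 3 rotation matrix.
#' @param ok_source logical; which parcels may donate values.
#' @param sphere internal override of the centroid matrix.
#' @return integer vector: `out[i]` is the source parcel whose rotated
#'   centroid lies closest to original parcel `i`.
#' @export
spin_assign <- function(geometry, rotation,
                        ok_source = !geometry$medial_wall,
                        sphere = geometry$sphere_xyz) {
  rot <- sphere %*% t(rotation)
  sim <- sphere %*% t(rot)            # cos(angle orig_i, rotated_j)
  sim[, !ok_source] <- -Inf
  max.col(sim, ties.method = "first")
}

#' Spin-permutation p-value for a map statistic
#'
#' Recomputes `statistic_fn(rotated A, B)` under every rotation of the
#' log. `mapA` may be a matrix (parcels x parameters); all its columns
#' are rotated with the same index set within a permutation. Rotations
#' on which the statistic is undefined (e.g. all-missing overlap) are
#' skipped and counted. The p-value uses the add-one correction
#' `p = (1 + #{null >= observed}) / (1 + n_used)` on `|statistic|` for
#' the default two-sided test.
#'
#' @param statistic_fn function of (A, B) returning a scalar.
#' @param mapA numeric vector or parcels x parameters matrix (rotated).
#' @param mapB second argument of the statistic (not rotated).
#' @param rotation_log a [spin_rotations()] log.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return `spatial_stat_result` with the observed value, p-value and
#'   the null distribution.
#' @export
spin_pvalue <- function(statistic_fn, mapA, mapB, rotation_log,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  A <- if (is.matrix(mapA)) mapA else matrix(as.numeric(mapA), ncol = 1)
  if (nrow(A) != attr(rotation_log, "n_parcels"))
    stop_invalid("map length does not match rotation log")
  obs <- statistic_fn(if (ncol(A) == 1L) A[, 1] else A, mapB)
  null <- apply(rotation_log, 1, function(idx) {
    Ar <- A[idx, , drop = FALSE]
    tryCatch(statistic_fn(if (ncol(Ar) == 1L) Ar[, 1] else Ar, mapB),
             error = function(e) NA_real_)
  })
  skipped <- sum(is.na(null))
  null <- null[!is.na(null)]
  exceed <- if (alternative == "two.sided") abs(null) >= abs(obs)
            else null >= obs
  spatial_stat_result("spin_statistic", obs,
                      p_value = (1 + sum(exceed)) / (1 + length(null)),
                      null_values = null, n_skipped = skipped)
}

#' Container for a map-level statistic
#' @param statistic_name label, e.g. `"spearman_rho"`.
#' @param value observed value.
#' @param p_value p-value (NA allowed).
#' @param ci optional `c(lo, hi)`.
#' @param ... further fields (e.g. `null_values`).
#' @export
spatial_stat_result <- function(statistic_name, value, p_value = NA_real_,
                                ci = NULL, ...) {
  structure(list(statistic = statistic_name, value = value,
                 p_value = p_value, ci = ci, ...),
            class = "spatial_stat_result")
}

#' @export
print.spatial_stat_result <- function(x, ...) {
  cat(sprintf("<%s> value = %.4f, p = %s%s\n", x$statistic, x$value,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value),
              if (!is.null(x$ci)) sprintf(", CI [%.4f, %.4f]",
                                          x$ci[1], x$ci[2]) else ""))
  invisible(x)
}

#' Polynomial fit of a map along an anatomical axis
#'
#' Projects parcels onto an anatomical axis (x = left-right,
#' y = posterior-anterior, z = inferior-superior, or the y+z diagonal;
#' the axis is standardized before fitting) and fits polynomials of
#' increasing order, stopping when order n+1 no longer improves on
#' order n by the nested-model F test at `alpha`. Reports the last
#' accepted order, its coefficients (highest power first, on the
#' standardized axis), R^2 and the overall F-test p-value.
#'
#' @param map numeric map (NA allowed).
#' @param geometry a [parcel_geometry()].
#' @param axis one of `"x"`, `"y"`, `"z"`, `"y_plus_z"`.
#' @param alpha significance level of the nested F test.
#' @param max_order largest order considered.
#' @return `axis_fit_result`: list(axis, order, coefficients,
#'   r_squared, p_value).
#' @export
axis_projection_fit <- function(map, geometry,
                                axis = c("x", "y", "z", "y_plus_z"),
                                alpha = 0.05, max_order = 5L) {
  axis <- match.arg(axis)
  a <- geometry$anat_xyz
  x <- switch(axis, x = a[, 1], y = a[, 2], z = a[, 3],
              y_plus_z = a[, 2] + a[, 3])
  y <- as.numeric(map)
  ok <- !is.na(y) & !is.na(x)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0) stop_invalid("degenerate axis values")
  x <- (x - mean(x)) / sd(x)
  if (length(y) < 4L) stop_invalid("too few non-missing parcels")
  fit_n <- function(n) lm(y ~ poly(x, n, raw = TRUE))
  order <- 1L
  fit <- fit_n(1L)
  while (order < max_order && length(y) >= order + 3L) {
    fit2 <- fit_n(order + 1L)
    p_impr <- anova(fit, fit2)[2, "Pr(>F)"]
    if (!is.finite(p_impr) || p_impr >= alpha) break
    order <- order + 1L
    fit <- fit2
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(axis = axis, order = order,
                 coefficients = rev(unname(coef(fit))),
                 r_squared = sm$r.squared,
                 p_value = unname(pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE))),
            class = "axis_fit_result")
}

#' @export
print.axis_fit_result <- function(x, ...) {
  cat(sprintf("<axis_fit> axis=%s order=%d R2=%.3f p=%s\n", x$axis,
              x$order, x$r_squared, format.pval(x$p_value)))
  invisible(x)
}

#' Moran's I spatial autocorrelation of a parcel map
#'
#' Standard Moran's I with row-normalized weights over non-missing
#' parcels. By default the weight graph is k-nearest-neighbour (k = 6)
#' on great-circle distances between spherical centroids; an explicit
#' (unnormalized) weight matrix can be supplied instead.
#'
#' @param map numeric map (NA allowed).
#' @param geometry a [parcel_geometry()] (required unless `weights`
#'   given).
#' @param weights optional n x n nonnegative weight matrix.
#' @param k neighbours for the default knn graph.
#' @param n_perm optional number of value permutations for a two-sided
#'   p-value (0 = no test).
#' @param seed seed for the permutation test.
#' @return `spatial_stat_result` with `value` = I and `expectation`
#'   = -1/(n-1).
#' @export
morans_i <- function(map, geometry = NULL, weights = NULL, k = 6L,
                     n_perm = 0L, seed = 1L) {
  y <- as.numeric(map)
  ok <- !is.na(y)
  if (sum(ok) < 3L) stop_invalid("need >= 3 non-missing parcels")
  if (is.null(weights)) {
    if (is.null(geometry)) stop_invalid("need geometry or weights")
    D <- greatcircle_dist(geometry)[ok, ok, drop = FALSE]
    n <- nrow(D)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, -i])[seq_len(min(k, n - 1L))]
      W[i, setdiff(seq_len(n), i)[nb]] <- 1
    }
  } else {
    W <- as.matrix(weights)[ok, ok, drop = FALSE]
    diag(W) <- 0
  }
  rs <- rowSums(W)
  if (any(rs == 0)) stop_invalid("isolated parcel in weight graph")
  W <- W / rs
  z <- y[ok] - mean(y[ok])
  if (sum(z^2) == 0) stop_invalid("degenerate input: zero variance")
  i_of <- function(z) sum(z * (W %*% z)) / sum(z^2)
  obs <- i_of(z)
  p <- NA_real_
  if (n_perm > 0) {
    nullv <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      zp <- z[sample.int(length(z))]
      i_of(zp)
    }, numeric(1)))
    e0 <- -1 / (length(z) - 1)
    p <- (1 + sum(abs(nullv - e0) >= abs(obs - e0))) / (1 + n_perm)
  }
  spatial_stat_result("morans_I", obs, p_value = p,
                      expectation = -1 / (sum(ok) - 1))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (or elements) of `sample` with replacement `n_boot`
#' times and returns the percentile interval of the statistic.
#' Resamples on which the statistic is undefined (error or NA) are
#' redrawn and counted in attribute `n_redrawn`.
#'
#' @param statistic_fn function of one resample.
#' @param sample vector, matrix or data.frame (rows resampled).
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level (0.95 gives the 2.5/97.5 percentiles).
#' @param seed integer seed.
#' @return numeric `c(lo, hi)` with attributes `n_redrawn`, `boot_values`.
#' @export
bootstrap_ci <- function(statistic_fn, sample, n_boot = 10000L,
                         level = 0.95, seed = 1L) {
  take <- function(s, idx) {
    if (is.null(dim(s))) s[idx] else s[idx, , drop = FALSE]
  }
  n <- if (is.null(dim(sample))) length(sample) else nrow(sample)
  if (n < 2L) stop_invalid("sample size must be >= 2")
  vals <- with_seed(seed, {
    out <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        v <- tryCatch(statistic_fn(take(sample, sample.int(n, replace = TRUE))),
                      error = function(e) NA_real_)
        if (is.finite(v)) break
        redrawn <- redrawn + 1L
        if (redrawn > 100L * n_boot)
          stop_invalid("statistic undefined on virtually all resamples")
      }
      out[b] <- v
    }
    attr(out, "n_redrawn") <- redrawn
    out
  })
  qs <- quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 6)
  structure(qs, n_redrawn = attr(vals, "n_redrawn"), boot_values = vals)
}
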