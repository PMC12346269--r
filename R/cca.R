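#' Canonical correlation analysis of two map sets (QR + SVD)
#'
#' Relates two parcels x parameters pattern matrices (e.g. psychosis
#' signature X and drug effect Y). Columns are centered; rows with any
#' missing entry in either matrix are dropped listwise (count reported
#' in `n_dropped`). The weights come from thin QR decompositions
#' `X = Qx Rx`, `Y = Qy Ry` and the SVD `Qx' Qy = U S V'`, with
#' `Wx = Rx^{-1} U`, `Wy = Ry^{-1} V`; the canonical correlations are
#' the singular values, reported in descending order. The first
#' canonical pair is sign-fixed so that the largest-magnitude X-side
#' loading is positive (both blocks flipped together, preserving the
#' sign of the correlation).
#'
#' @param X,Y numeric matrices with matching rows (parcels).
#' @return `cca_result`: list with `correlations`, `Wx`, `Wy`, `Zx`,
#'   `Zy`, `loadings_x`, `loadings_y`, `explained_fractions`,
#'   `n_dropped`, `rows_used`, and `diagnostics` (Qx, Rx, Qy, Ry, U, S,
#'   V) retained for verification.
#' @export
fit_cca <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_invalid("X and Y must share rows")
  ok <- complete.cases(X) & complete.cases(Y)
  n_dropped <- sum(!ok)
  Xc <- scale(X[ok, , drop = FALSE], center = TRUE, scale = FALSE)
  Yc <- scale(Y[ok, , drop = FALSE], center = TRUE, scale = FALSE)
  if (nrow(Xc) <= ncol(Xc) + ncol(Yc))
    stop_invalid("too few complete rows for CCA")
  qx <- qr(Xc); qy <- qr(Yc)
  Rx <- qr.R(qx); Ry <- qr.R(qy)
  bad <- function(R) which(abs(diag(R)) < max(abs(diag(R))) * 1e-10)
  if (length(c(bad(Rx)))) stop_invalid(
    "rank-deficient X: column(s) ", paste(bad(Rx), collapse = ", "))
  if (length(c(bad(Ry)))) stop_invalid(
    "rank-deficient Y: column(s) ", paste(bad(Ry), collapse = ", "))
  Qx <- qr.Q(qx); Qy <- qr.Q(qy)
  sv <- svd(crossprod(Qx, Qy))
  Wx <- backsolve(Rx, sv$u)
  Wy <- backsolve(Ry, sv$v)
  Zx <- Xc %*% Wx
  Zy <- Yc %*% Wy
  lx <- suppressWarnings(cor(X[ok, , drop = FALSE], Zx[, 1]))[, 1]
  ly <- suppressWarnings(cor(Y[ok, , drop = FALSE], Zy[, 1]))[, 1]
  if (any(!is.finite(lx)))
    warning("zero-variance X column(s): loading set to NA", call. = FALSE)
  s <- sign(lx[which.max(abs(lx))])
  if (is.finite(s) && s < 0) {
    Zx[, 1] <- -Zx[, 1]; Wx[, 1] <- -Wx[, 1]; lx <- -lx
    Zy[, 1] <- -Zy[, 1]; Wy[, 1] <- -Wy[, 1]; ly <- -ly
  }
  structure(list(
    correlations = sv$d,
    Wx = Wx, Wy = Wy, Zx = Zx, Zy = Zy,
    loadings_x = lx, loadings_y = ly,
    explained_fractions = sv$d^2 / sum(sv$d^2),
    n_dropped = n_dropped, rows_used = which(ok),
    diagnostics = list(Qx = Qx, Rx = Rx, Qy = Qy, Ry = Ry,
                       U = sv$u, S = diag(sv$d, length(sv$d)), V = sv$v)),
    class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> %d pairs, first R = %.3f (%d rows, %d dropped)\n",
              length(x$correlations), x$correlations[1],
              length(x$rows_used), x$n_dropped))
  invisible(x)
}

#' Fraction of covariance explained by each canonical pair
#'
#' `fraction_i = R_i^2 / sum_j R_j^2`; the eigenvalue spectrum of the
#' canonical decomposition.
#'
#' @param result a fitted [fit_cca()] result.
#' @export
explained_covariance <- function(result) {
  r2 <- result$correlations^2
  if (sum(r2) == 0) stop_invalid("all canonical correlations are zero")
  r2 / sum(r2)
}

#' Loadings of the first canonical pair
#'
#' Pearson correlations between each original parameter column and the
#' first canonical variable of its own block.
#'
#' @param result a fitted [fit_cca()] result.
#' @param X,Y the matrices the result was fitted on.
#' @return list(loadings_x, loadings_y), 6-vectors for 6 parameters.
#' @export
cca_loadings <- function(result, X, Y) {
  ok <- result$rows_used
  lx <- suppressWarnings(cor(as.matrix(X)[ok, , drop = FALSE],
                             result$Zx[, 1]))[, 1]
  ly <- suppressWarnings(cor(as.matrix(Y)[ok, , drop = FALSE],
                             result$Zy[, 1]))[, 1]
  if (any(!is.finite(c(lx, ly))))
    warning("zero-variance column(s): loading set to NA", call. = FALSE)
  list(loadings_x = lx, loadings_y = ly)
}

#' Spin-permutation significance of the first canonical correlation
#'
#' Rotates all columns of X with the same rotation within each
#' permutation, refits the CCA and records the first canonical
#' correlation. One-sided (canonical correlations are nonnegative),
#' with the add-one correction.
#'
#' @param X,Y pattern matrices.
#' @param rotation_log a [spin_rotations()] log on the matrices'
#'   geometry.
#' @return `spatial_stat_result` for the first canonical correlation.
#' @export
cca_significance <- function(X, Y, rotation_log) {
  X <- as.matrix(X)
  res <- spin_pvalue(function(A, B) fit_cca(A, B)$correlations[1],
                     X, Y, rotation_log, alternative = "greater")
  res$statistic <- "canonical_r"
  res
}

#' Reproducibility of CCA across repeated fits
#'
#' Given CCAs fitted on repeated splits/sessions over one shared
#' geometry, computes Spearman correlations between corresponding
#' first canonical variables across fits (X side and Y side
#' separately) and between the loading vectors; optionally spin
#' p-values for the map correlations.
#'
#' @param result_list list of [fit_cca()] results.
#' @param rotation_log optional [spin_rotations()] log for p-values of
#'   the canonical-variable map correlations.
#' @return list of symmetric matrices `zx_cross`, `zy_cross`,
#'   `loadings_x_cross`, `loadings_y_cross` and (optionally) `zx_p`,
#'   `zy_p`.
#' @export
cca_reproducibility <- function(result_list, rotation_log = NULL) {
  m <- length(result_list)
  if (m < 2L) stop_invalid("need >= 2 fitted CCAs")
  n_map <- if (is.null(rotation_log)) NA_integer_
           else attr(rotation_log, "n_parcels")
  full_vec <- function(res, side) {
    v <- rep(NA_real_, max(res$rows_used))
    v[res$rows_used] <- if (side == "x") res$Zx[, 1] else res$Zy[, 1]
    if (!is.na(n_map)) length(v) <- n_map
    v
  }
  out <- list()
  for (side in c("x", "y")) {
    cc <- matrix(1, m, m)
    pp <- matrix(NA_real_, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      vi <- full_vec(result_list[[i]], side)
      vj <- full_vec(result_list[[j]], side)
      if (length(vi) != length(vj))
        stop_invalid("mismatched geometries across fits")
      cc[i, j] <- cc[j, i] <- spearman_map_corr(vi, vj)
      if (!is.null(rotation_log)) {
        sp <- spin_pvalue(spearman_map_corr, vi, vj, rotation_log)
        pp[i, j] <- pp[j, i] <- sp$p_value
      }
    }
    out[[paste0("z", side, "_cross")]] <- cc
    if (!is.null(rotation_log)) out[[paste0("z", side, "_p")]] <- pp
    lc <- matrix(1, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      li <- if (side == "x") result_list[[i]]$loadings_x
            else result_list[[i]]$loadings_y
      lj <- if (side == "x") result_list[[j]]$loadings_x
            else result_list[[j]]$loadings_y
      lc[i, j] <- lc[j, i] <- cor(rank(li), rank(lj))
    }
    out[[paste0("loadings_", side, "_cross")]] <- lc
  }
  out
}
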