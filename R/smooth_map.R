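#' Cholesky factor for smooth Gaussian fields on a parcellation
#'
#' Precomputes the (upper) Cholesky factor of an exponential spatial
#' covariance \eqn{C_{ij} = \exp(-d_{ij}/\ell)} on great-circle
#' distances, so that many smooth maps can be drawn cheaply from one
#' geometry. The exponential kernel is positive definite on the sphere
#' for geodesic distance (unlike the squared-exponential), which keeps
#' the factorization stable.
#'
#' @param geometry a [parcel_geometry()].
#' @param length_scale spatial autocorrelation length (radians of arc).
#' @param jitter diagonal jitter for numerical positive-definiteness.
#' @return upper-triangular matrix `L` with `crossprod(L) = C`.
#' @export
smooth_map_factor <- function(geometry, length_scale, jitter = 1e-8) {
  if (!is.numeric(length_scale) || length_scale <= 0)
    stop_invalid("length_scale must be > 0")
  D <- greatcircle_dist(geometry)
  if (max(D) < 1e-12)
    stop_invalid("degenerate geometry: all centroids coincide")
  C <- exp(-D / length_scale)
  chol(C + diag(jitter, nrow(C)))
}

#' Simulate spatially autocorrelated parcel maps
#'
#' Draws zero-mean unit-variance Gaussian fields over parcels whose
#' covariance decays exponentially with great-circle distance at
#' `length_scale`. These are the null maps used to exercise and
#' calibrate the spin-rotation permutation test.
#'
#' @inheritParams smooth_map_factor
#' @param seed integer seed (deterministic output).
#' @param n_maps number of independent maps to draw.
#' @param factor optional precomputed [smooth_map_factor()] (must match
#'   `geometry`/`length_scale`); avoids refactorizing in tight loops.
#' @return a [parcel_map()] if `n_maps = 1`, else an
#'   `n_parcels x n_maps` matrix.
#' @export
simulate_smooth_map <- function(geometry, length_scale, seed,
                                n_maps = 1L, factor = NULL) {
  L <- factor %||% smooth_map_factor(geometry, length_scale)
  n <- n_parcels(geometry)
  Z <- with_seed(seed, matrix(rnorm(n * n_maps), n, n_maps))
  M <- crossprod(L, Z)
  if (n_maps == 1L) parcel_map(M[, 1], geometry, "smooth_field") else M
}
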