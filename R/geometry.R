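#' Parcellation geometry
#'
#' A `parcel_geometry` holds, for each cortical parcel, a centroid on the
#' unit sphere (the support of spin-rotation permutations) and a centroid
#' in anatomical space (MNI-like axes: x = left-right, y =
#' posterior-anterior, z = inferior-superior), plus a medial-wall flag.
#' An optional homotopic pairing table links left/right parcels so that
#' hemisphere averaging is possible.
#'
#' @param parcel_id integer vector of unique parcel labels.
#' @param sphere_xyz n x 3 matrix of unit-norm spherical centroids.
#' @param anat_xyz n x 3 matrix of anatomical centroids (mm).
#' @param medial_wall logical vector flagging medial-wall parcels.
#' @param homotopic_pairs optional data.frame with integer columns
#'   `left`, `right` holding row indices of paired parcels; each parcel
#'   appears exactly once.
#' @return An object of class `parcel_geometry`.
#' @export
parcel_geometry <- function(parcel_id, sphere_xyz, anat_xyz,
                            medial_wall = rep(FALSE, length(parcel_id)),
                            homotopic_pairs = NULL) {
  sphere_xyz <- as.matrix(sphere_xyz)
  anat_xyz <- as.matrix(anat_xyz)
  n <- length(parcel_id)
  if (anyDuplicated(parcel_id))
    stop_invalid("parcel_id must be unique")
  if (nrow(sphere_xyz) != n || ncol(sphere_xyz) != 3L)
    stop_invalid("sphere_xyz must be an n x 3 matrix")
  if (nrow(anat_xyz) != n || ncol(anat_xyz) != 3L)
    stop_invalid("anat_xyz must be an n x 3 matrix")
  nrm <- sqrt(rowSums(sphere_xyz^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop_invalid("sphere_xyz rows must have unit norm (tolerance 1e-9)")
  medial_wall <- as.logical(medial_wall)
  if (length(medial_wall) != n) stop_invalid("medial_wall length mismatch")
  # the spin statistics need >= 3 usable parcels once a medial wall
  # exists; trivial geometries without one are allowed (identity cases)
  if (any(medial_wall) && sum(!medial_wall) < 3L)
    stop_invalid("need at least 3 non-medial-wall parcels")
  if (!is.null(homotopic_pairs)) {
    hp <- as.data.frame(homotopic_pairs)
    idx <- c(hp$left, hp$right)
    if (anyDuplicated(idx) || !setequal(idx, seq_len(n)))
      stop_invalid("homotopic_pairs must cover every parcel exactly once")
  }
  structure(
    list(parcel_id = as.integer(parcel_id),
         sphere_xyz = unname(sphere_xyz),
         anat_xyz = unname(anat_xyz),
         medial_wall = medial_wall,
         homotopic_pairs = if (is.null(homotopic_pairs)) NULL
                           else as.data.frame(homotopic_pairs)),
    class = "parcel_geometry")
}

#' @export
print.parcel_geometry <- function(x, ...) {
  cat(sprintf("<parcel_geometry> %d parcels (%d medial wall)%s\n",
              n_parcels(x), sum(x$medial_wall),
              if (!is.null(x$homotopic_pairs))
                sprintf(", %d homotopic pairs", nrow(x$homotopic_pairs))
              else ""))
  invisible(x)
}

#' Number of parcels in a geometry
#' @param geometry a [parcel_geometry()].
#' @export
n_parcels <- function(geometry) length(geometry$parcel_id)

# Fixed affine taking unit-sphere coordinates to an MNI-like box. Only
# the axis semantics matter downstream (x LR, y PA, z IS).
.sphere_to_anat <- function(xyz) {
  sweep(xyz %*% diag(c(70, 85, 75)), 2, c(0, -18, 15), `+`)
}

#' Quasi-uniform spherical parcellation surrogate
#'
#' Places `n_parcels` centroids quasi-uniformly on the unit sphere using
#' a Fibonacci lattice, applies a random (seed-determined) global
#' rotation, and derives anatomical centroids by a fixed affine map.
#' Serves as a stand-in for an MRI-derived parcellation: it preserves
#' the only properties the spatial statistics consume (spherical
#' positions, pairwise distances, anatomical axes).
#'
#' @param n_parcels number of parcels (>= 1).
#' @param seed integer seed; the lattice is deterministic, the seed
#'   fixes its global orientation.
#' @param n_medial number of parcels to flag as medial wall (the ones
#'   closest to the x = 0 plane); default 0.
#' @return A [parcel_geometry()].
#' @export
make_geometry <- function(n_parcels, seed = 1L, n_medial = 0L) {
  if (!is.numeric(n_parcels) || n_parcels < 1)
    stop_invalid("n_parcels must be a positive integer")
  n <- as.integer(n_parcels)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  xyz <- cbind(r * cos(phi), r * sin(phi), z)
  R <- with_seed(seed, random_rotation_matrix())
  xyz <- xyz %*% t(R)
  xyz <- xyz / sqrt(rowSums(xyz^2))
  medial <- rep(FALSE, n)
  if (n_medial > 0) {
    if (n - n_medial < 3L) stop_invalid("too many medial-wall parcels")
    medial[order(abs(xyz[, 1]))[seq_len(n_medial)]] <- TRUE
  }
  parcel_geometry(seq_len(n), xyz, .sphere_to_anat(xyz), medial)
}

#' Bilateral geometry with homotopic pairing
#'
#' Builds `n_pairs` right-hemisphere centroids by Fibonacci lattice and
#' mirrors them across the x = 0 plane, yielding 2 x `n_pairs` parcels
#' with an explicit homotopic pairing table (left parcel i pairs with
#' right parcel i + n_pairs), so that [average_hemispheres()] is
#' exercisable on synthetic cohorts.
#'
#' @param n_pairs number of homotopic pairs.
#' @inheritParams make_geometry
#' @return A [parcel_geometry()] with `homotopic_pairs`.
#' @export
make_bilateral_geometry <- function(n_pairs, seed = 1L) {
  if (!is.numeric(n_pairs) || n_pairs < 2)
    stop_invalid("n_pairs must be >= 2")
  g <- make_geometry(n_pairs, seed = seed)
  right <- g$sphere_xyz
  # push centroids off the mirror plane so L/R do not coincide
  right[, 1] <- abs(right[, 1]) + 0.05
  right <- right / sqrt(rowSums(right^2))
  left <- right
  left[, 1] <- -left[, 1]
  xyz <- rbind(left, right)
  pairs <- data.frame(left = seq_len(n_pairs),
                      right = seq_len(n_pairs) + n_pairs)
  parcel_geometry(seq_len(2L * n_pairs), xyz, .sphere_to_anat(xyz),
                  homotopic_pairs = pairs)
}

#' Great-circle distance matrix between parcel centroids
#' @param geometry a [parcel_geometry()].
#' @return n x n matrix of great-circle distances (radians).
#' @export
greatcircle_dist <- function(geometry) {
  s <- geometry$sphere_xyz
  cosd <- tcrossprod(s)
  cosd[] <- pmin(1, pmax(-1, cosd))
  acos(cosd)
}

# Uniform random rotation matrix from a normalized quaternion.
random_rotation_matrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
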