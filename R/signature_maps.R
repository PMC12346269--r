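#' Average homotopic hemispheres
#'
#' Collapses a bilateral map to one value per homotopic pair: the mean
#' of the left/right values; if one side is missing the other side's
#' value is used; if both are missing the result is missing. Commutes
#' with any scaling of the map.
#'
#' @param map_2h numeric map over all parcels of a bilateral geometry.
#' @param homotopic_pairs data.frame with `left`, `right` row indices
#'   covering every parcel exactly once (as in
#'   [make_bilateral_geometry()]).
#' @return numeric vector of length `nrow(homotopic_pairs)`.
#' @export
average_hemispheres <- function(map_2h, homotopic_pairs) {
  hp <- as.data.frame(homotopic_pairs)
  idx <- c(hp$left, hp$right)
  if (anyDuplicated(idx) || !setequal(idx, seq_along(map_2h)))
    stop_invalid("homotopic_pairs must cover every parcel exactly once")
  l <- map_2h[hp$left]
  r <- map_2h[hp$right]
  out <- (l + r) / 2
  out[is.na(l)] <- r[is.na(l)]
  out[is.na(r)] <- l[is.na(r)]
  out
}

#' z-score a map across parcels
#'
#' Centers and scales over non-missing parcels; missing entries are
#' preserved in place. Rank order is preserved.
#'
#' @param map numeric map (NA allowed).
#' @export
zscore_map <- function(map) {
  v <- as.numeric(map)
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop_invalid("need >= 2 non-missing values")
  s <- sd(v[ok])
  if (s == 0) stop_invalid("degenerate input: map has zero variance")
  v[ok] <- (v[ok] - mean(v[ok])) / s
  v
}

#' Group-difference map between two collections of subject maps
#'
#' `mean_diff` gives mean(A) - mean(B) per parcel (the analysis path,
#' applied to z-scored maps to form psychosis signatures); `t_score`
#' gives the pooled-variance two-sample t statistic (display path).
#' Per-parcel means are taken over subjects with available values;
#' parcels failing the mode's minimum counts (1 per group for
#' mean_diff, 2 for t) are missing. An error is raised only when every
#' parcel fails.
#'
#' @param groupA_maps,groupB_maps subjects x parcels matrices.
#' @param mode `"mean_diff"` (default) or `"t_score"`.
#' @return numeric map with attributes `mode`, `n_A`, `n_B`.
#' @export
group_difference_map <- function(groupA_maps, groupB_maps,
                                 mode = c("mean_diff", "t_score")) {
  mode <- match.arg(mode)
  A <- as.matrix(groupA_maps)
  B <- as.matrix(groupB_maps)
  if (ncol(A) != ncol(B)) stop_invalid("parcel counts differ")
  nA <- colSums(!is.na(A)); nB <- colSums(!is.na(B))
  mA <- colMeans(A, na.rm = TRUE); mB <- colMeans(B, na.rm = TRUE)
  if (mode == "mean_diff") {
    out <- mA - mB
    out[nA < 1 | nB < 1] <- NA_real_
  } else {
    vA <- apply(A, 2, var, na.rm = TRUE)
    vB <- apply(B, 2, var, na.rm = TRUE)
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    out <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
    # zero-variance parcels: identical groups give t = 0, not 0/0
    degen <- sp2 == 0 & abs(mA - mB) < 1e-12
    out[!is.na(degen) & degen] <- 0
    out[nA < 2 | nB < 2] <- NA_real_
  }
  if (all(is.na(out)))
    stop_invalid("no parcel satisfies the per-group subject minimum")
  structure(out, mode = mode, n_A = nrow(A), n_B = nrow(B))
}

#' Within-subject drug-effect map
#'
#' For each subject present in both conditions, z-scores the drug and
#' placebo maps across parcels and subtracts placebo from drug; the
#' effect map is the mean of these within-subject differences.
#' Subjects missing from either condition are excluded with a warning;
#' if no pair remains an error is raised.
#'
#' @param drug_subject_maps,placebo_subject_maps subjects x parcels
#'   matrices with subject ids as row names.
#' @param zscore z-score each subject map before differencing
#'   (default TRUE, the analysis path).
#' @return numeric map with attribute `n_pairs`.
#' @export
drug_effect_map <- function(drug_subject_maps, placebo_subject_maps,
                            zscore = TRUE) {
  D <- as.matrix(drug_subject_maps)
  P <- as.matrix(placebo_subject_maps)
  if (is.null(rownames(D)) || is.null(rownames(P)))
    stop_invalid("subject ids required as row names")
  ids <- intersect(rownames(D), rownames(P))
  dropped <- setdiff(union(rownames(D), rownames(P)), ids)
  if (length(dropped))
    warning("excluding unpaired subject(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (!length(ids)) stop_invalid("no paired subjects")
  diffs <- vapply(ids, function(id) {
    d <- D[id, ]; p <- P[id, ]
    if (zscore) { d <- zscore_map(d); p <- zscore_map(p) }
    d - p
  }, numeric(ncol(D)))
  structure(rowMeans(diffs, na.rm = TRUE), n_pairs = length(ids),
            mode = "mean_diff")
}
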