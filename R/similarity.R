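#' Concatenate parameter maps vertically into one subject vector
#'
#' Stacks the six parameter maps in the fixed canonical order
#' [DYNAMICS_PARAMETERS] (parcels in geometry order within each
#' block), yielding a vector of length `n_parameters * n_parcels`
#' (1080 for 6 x 180). Input order is irrelevant; maps are looked up
#' by name.
#'
#' @param subject_maps named list of per-parameter numeric maps.
#' @param parameter_order stacking order, default [DYNAMICS_PARAMETERS].
#' @export
concat_parameters_vertical <- function(subject_maps,
                                       parameter_order = DYNAMICS_PARAMETERS) {
  unknown <- setdiff(names(subject_maps), parameter_order)
  if (length(unknown))
    stop_invalid("unknown parameter label(s): ",
                 paste(unknown, collapse = ", "))
  missing_p <- setdiff(parameter_order, names(subject_maps))
  if (length(missing_p))
    stop_invalid("missing parameter map(s): ",
                 paste(missing_p, collapse = ", "))
  lens <- lengths(subject_maps)
  if (length(unique(lens)) != 1L)
    stop_invalid("all parameter maps must share one geometry")
  unlist(lapply(parameter_order,
                function(p) as.numeric(subject_maps[[p]])),
         use.names = FALSE)
}

#' Similarity of an individual signature to a reference effect vector
#'
#' Correlates a subject's concatenated individual signature vector `u`
#' (z-scored per-parameter maps minus the control-group mean maps)
#' with a concatenated reference drug-effect vector `v_ref`, over
#' jointly non-missing entries. The spin p-value applies one shared
#' rotation across all parameter blocks per permutation.
#'
#' @param u_i,v_ref concatenated vectors of length
#'   `n_parameters * n_parcels`.
#' @param rotation_log a [spin_rotations()] log on the underlying
#'   parcellation (block length inferred from it); NULL skips the test.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_overlap minimum jointly non-missing entries.
#' @return list(r, p) (`p` NA without a rotation log).
#' @export
individual_similarity <- function(u_i, v_ref, rotation_log = NULL,
                                  method = c("spearman", "pearson"),
                                  min_overlap = 30L) {
  method <- match.arg(method)
  u <- as.numeric(u_i); v <- as.numeric(v_ref)
  if (length(u) != length(v)) stop_invalid("vector lengths differ")
  ok <- !is.na(u) & !is.na(v)
  if (sum(ok) < min_overlap)
    stop_invalid("overlap < ", min_overlap, " entries")
  stat <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < min_overlap) stop_invalid("overlap too small")
    if (method == "spearman") cor(rank(a[keep]), rank(b[keep]))
    else cor(a[keep], b[keep])
  }
  r <- stat(u, v)
  p <- NA_real_
  if (!is.null(rotation_log)) {
    np <- attr(rotation_log, "n_parcels")
    if (length(u) %% np != 0)
      stop_invalid("vector length not a multiple of the parcel count")
    U <- matrix(u, nrow = np)          # parcels x parameters
    res <- spin_pvalue(function(A, B) stat(as.numeric(A), B),
                       U, v, rotation_log)
    p <- res$p_value
  }
  list(r = r, p = p)
}

#' Correlation of individual similarities with symptom scores
#'
#' Rank (or Pearson) correlation between per-subject similarity values
#' and aggregate symptom scores, with a two-sided p-value from
#' permuting scores across subjects (subject-level exchangeability; a
#' spatial null is not applicable here). Add-one correction.
#'
#' @param similarities numeric vector, one value per subject.
#' @param symptom_scores numeric vector, same subjects.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return `spatial_stat_result` (statistic `symptom_corr`).
#' @export
symptom_correlation <- function(similarities, symptom_scores,
                                n_perm = 10000L, seed = 1L,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  r <- as.numeric(similarities); s <- as.numeric(symptom_scores)
  ok <- !is.na(r) & !is.na(s)
  r <- r[ok]; s <- s[ok]
  n <- length(r)
  if (n < 5L) stop_invalid("need >= 5 paired subjects")
  if (sd(s) == 0) stop_invalid("degenerate input: constant scores")
  if (method == "spearman") { r <- rank(r); s <- rank(s) }
  obs <- cor(r, s)
  zr <- (r - mean(r)) / sd(r)
  zs <- (s - mean(s)) / sd(s)
  null <- with_seed(seed, {
    P <- vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
    as.numeric(crossprod(zs[P] |> matrix(nrow = n), zr)) / (n - 1)
  })
  spatial_stat_result("symptom_corr", obs,
                      p_value = (1 + sum(abs(null) >= abs(obs))) /
                        (1 + n_perm),
                      null_values = null)
}

#' Double-dissociation permutation test (drug x symptom dimension)
#'
#' Interaction statistic
#' `D = [z(sim_A, pos) - z(sim_A, neg)] - [z(sim_B, pos) - z(sim_B, neg)]`,
#' where `z` is the Fisher-transformed correlation (the standard
#' variance-stabilized scale for comparing correlations; set
#' `fisher = FALSE` for raw correlations). The null jointly permutes
#' each subject's (positive, negative) score pair across subjects,
#' preserving the dependence between the two symptom dimensions.
#' Two-sided p with add-one correction. Swapping the two similarity
#' vectors negates D exactly.
#'
#' @param sim_A,sim_B per-subject similarities to the two drug
#'   patterns.
#' @param positive_scores,negative_scores aggregate symptom scores.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param fisher compare correlations on the Fisher-z scale (default).
#' @return `spatial_stat_result` (statistic `double_dissociation`).
#' @export
double_dissociation_test <- function(sim_A, sim_B, positive_scores,
                                     negative_scores, n_perm = 2000L,
                                     seed = 1L,
                                     method = c("spearman", "pearson"),
                                     fisher = TRUE) {
  method <- match.arg(method)
  n <- length(sim_A)
  if (length(sim_B) != n || length(positive_scores) != n ||
      length(negative_scores) != n)
    stop_invalid("all four vectors must be paired over the same subjects")
  if (n < 8L) stop_invalid("n < 8: test uninformative")
  prep <- function(v) {
    v <- as.numeric(v)
    if (method == "spearman") v <- rank(v)
    (v - mean(v)) / sd(v)
  }
  za <- prep(sim_A); zb <- prep(sim_B)
  zp <- prep(positive_scores); zn <- prep(negative_scores)
  cval <- if (fisher) {
    function(a, b) atanh(min(max(sum(a * b) / (n - 1), -1 + 1e-12),
                             1 - 1e-12))
  } else {
    function(a, b) sum(a * b) / (n - 1)
  }
  delta <- function(p, q) {
    (cval(za, p) - cval(za, q)) - (cval(zb, p) - cval(zb, q))
  }
  obs <- delta(zp, zn)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n)
      delta(zp[idx], zn[idx])
    }, numeric(1))
  })
  spatial_stat_result("double_dissociation", obs,
                      p_value = (1 + sum(abs(null) >= abs(obs))) /
                        (1 + n_perm),
                      null_values = null)
}
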