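#' Configuration of a synthetic cohort
#'
#' Describes the generative world the pipeline is tested against:
#' a (bilateral) spherical parcellation, a hierarchy-like gradient map,
#' smooth per-parameter signature patterns of the embedded group
#' difference, per-subject expression \eqn{\beta_i \sim
#' N(\beta, \beta/2)} truncated at 0, smooth subject noise, symptom
#' scores linearly coupled to the individual expression, and the
#' per-parcel time-series parameters used when cohorts are emitted as
#' raw signals. Maps are produced in natural parameter units:
#' `map = mean_p + sd_p * (gradient_loading * gradient +
#' beta_i * signature_p + noise)`.
#'
#' @param seed master seed; all sub-generators derive from it.
#' @param geometry_seed seed of the parcellation geometry (defaults to
#'   `seed`); fixing it across cohorts keeps the geometry — and hence
#'   precomputed spin-rotation logs — shared while data vary.
#' @param n_parcels total parcel count (even when `bilateral`).
#' @param bilateral build the geometry as homotopic left/right pairs.
#' @param group_sizes named vector, e.g. `c(control = 40, clinical = 40)`;
#'   groups whose name is not `"control"` carry the signature.
#' @param beta mean signature expression in clinical groups.
#' @param noise_sd SD of the smooth subject noise (standardized units).
#' @param smoothness_length_scale spatial autocorrelation length (rad).
#' @param gradient_loading weight of the hierarchy gradient in every
#'   parameter map.
#' @param symptom_coupling coefficients `c(positive=, negative=)`
#'   linking symptom scores to `beta_i`.
#' @param symptom_noise_sd SD of the symptom noise.
#' @param drug_group_size if > 0, adds within-subject pharmacology
#'   subjects, each with a placebo condition and one condition per
#'   entry of `drug_names`.
#' @param drug_names condition labels of the drug effects.
#' @param drug_beta mean expression of the drug patterns.
#' @param gradient_map optional externally supplied gradient (length
#'   `n_parcels`).
#' @param signature_patterns optional `n_parcels x 6` matrix of the
#'   embedded difference patterns (columns [DYNAMICS_PARAMETERS]).
#' @param parameter_means,parameter_sds natural-unit location/scale of
#'   the six parameters (`auc` mean `NA` = derived from the
#'   time-series defaults).
#' @param timeseries list(fs, duration, alpha_bandwidth) used when
#'   emitting per-parcel signals.
#' @export
synthetic_config <- function(seed = 1L,
                             geometry_seed = seed,
                             n_parcels = 360L,
                             bilateral = TRUE,
                             group_sizes = c(control = 40L, clinical = 40L),
                             beta = 1,
                             noise_sd = 0.5,
                             smoothness_length_scale = 0.3,
                             gradient_loading = 1,
                             symptom_coupling = c(positive = 1.15,
                                                  negative = 0),
                             symptom_noise_sd = 1,
                             drug_group_size = 0L,
                             drug_names = c("drug_A", "drug_B"),
                             drug_beta = 1,
                             gradient_map = NULL,
                             signature_patterns = NULL,
                             parameter_means = c(exponent = 2,
                                                 knee_frequency = 5,
                                                 auc = NA,
                                                 hurst = 0.7,
                                                 alpha_power = 0.8,
                                                 alpha_frequency = 10),
                             parameter_sds = c(exponent = 0.25,
                                               knee_frequency = 1,
                                               auc = NA,
                                               hurst = 0.08,
                                               alpha_power = 0.15,
                                               alpha_frequency = 0.5),
                             timeseries = list(fs = 250, duration = 300,
                                               alpha_bandwidth = 4)) {
  if (any(group_sizes < 2L)) stop_invalid("group sizes must be >= 2")
  if (noise_sd <= 0) stop_invalid("noise_sd must be > 0")
  if (bilateral && n_parcels %% 2L != 0L)
    stop_invalid("bilateral geometry needs an even n_parcels")
  # derive the natural AUC scale from the default aperiodic model
  if (is.na(parameter_means["auc"])) {
    base <- summarize_spectrum(list(offset = 1,
                                    knee = parameter_means[["knee_frequency"]]^
                                      parameter_means[["exponent"]],
                                    exponent = parameter_means[["exponent"]],
                                    mode = "with_knee",
                                    knee_frequency = NA))
    parameter_means["auc"] <- base$auc
  }
  if (is.na(parameter_sds["auc"]))
    parameter_sds["auc"] <- 0.15 * parameter_means[["auc"]]
  structure(list(seed = as.integer(seed),
                 geometry_seed = as.integer(geometry_seed),
                 n_parcels = as.integer(n_parcels),
                 bilateral = bilateral, group_sizes = group_sizes,
                 beta = beta, noise_sd = noise_sd,
                 smoothness_length_scale = smoothness_length_scale,
                 gradient_loading = gradient_loading,
                 symptom_coupling = symptom_coupling,
                 symptom_noise_sd = symptom_noise_sd,
                 drug_group_size = as.integer(drug_group_size),
                 drug_names = drug_names, drug_beta = drug_beta,
                 gradient_map = gradient_map,
                 signature_patterns = signature_patterns,
                 parameter_means = parameter_means,
                 parameter_sds = parameter_sds,
                 timeseries = timeseries),
            class = "synthetic_config")
}

# truncated-at-zero normal via rejection
.rtruncnorm0 <- function(n, mean, sd) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, mean, sd)
      if (v >= 0) break
    }
    out[i] <- v
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Control subjects express the gradient plus smooth noise in each
#' parameter map; clinical subjects additionally add
#' `beta_i * signature_pattern`; pharmacology subjects (when
#' configured) have a placebo condition and one condition per drug,
#' the latter adding `beta_i * drug_pattern`. Symptom scores are
#' `coupling * beta_i + noise` for clinical subjects. Fully
#' reproducible given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return A `cohort`: list(geometry, subjects, truth, config).
#'   Each subject is a list(subject_id, group_label, maps, symptoms,
#'   beta); `maps` is a named list of conditions, each a
#'   `n_parcels x 6` matrix in natural units.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  has_clinical <- any(names(cf$group_sizes) != "control")
  if ((has_clinical && cf$beta != 0) || cf$drug_group_size > 0) {
    # signature patterns required (generated below when absent)
  }
  geometry <- if (cf$bilateral)
    make_bilateral_geometry(cf$n_parcels %/% 2L, seed = cf$geometry_seed)
  else make_geometry(cf$n_parcels, seed = cf$geometry_seed)
  n <- n_parcels(geometry)
  L <- smooth_map_factor(geometry, cf$smoothness_length_scale)

  gradient <- cf$gradient_map %||% {
    g <- zscore_map(geometry$anat_xyz[, 2] + geometry$anat_xyz[, 3])
    pert <- simulate_smooth_map(geometry, cf$smoothness_length_scale,
                                seed = cf$seed + 11L, factor = L)
    zscore_map(g + 0.3 * map_values(pert))
  }
  if (length(gradient) != n) stop_invalid("gradient_map length mismatch")

  signature <- cf$signature_patterns %||% {
    M <- simulate_smooth_map(geometry, cf$smoothness_length_scale,
                             seed = cf$seed + 23L, n_maps = 6L, factor = L)
    apply(M, 2, zscore_map)
  }
  signature <- as.matrix(signature)
  if (nrow(signature) != n || ncol(signature) != 6L)
    stop_invalid("signature_patterns must be n_parcels x 6")
  colnames(signature) <- DYNAMICS_PARAMETERS
  if (has_clinical && cf$beta != 0 && all(signature == 0))
    stop_invalid("signature_patterns required when beta != 0")

  drug_patterns <- NULL
  if (cf$drug_group_size > 0) {
    drug_patterns <- lapply(seq_along(cf$drug_names), function(d) {
      M <- simulate_smooth_map(geometry, cf$smoothness_length_scale,
                               seed = cf$seed + 101L * d, n_maps = 6L,
                               factor = L)
      M <- apply(M, 2, zscore_map)
      colnames(M) <- DYNAMICS_PARAMETERS
      M
    })
    names(drug_patterns) <- cf$drug_names
  }

  mk_maps <- function(field) {
    # field: n x 6 standardized deviations -> natural units
    M <- sweep(field, 2, cf$parameter_sds[DYNAMICS_PARAMETERS], `*`)
    M <- sweep(M, 2, cf$parameter_means[DYNAMICS_PARAMETERS], `+`)
    colnames(M) <- DYNAMICS_PARAMETERS
    M
  }

  subjects <- list()
  sid <- 0L
  out <- with_seed(cf$seed + 1000L, {
    for (g in names(cf$group_sizes)) {
      is_clin <- g != "control"
      for (i in seq_len(cf$group_sizes[[g]])) {
        sid <- sid + 1L
        beta_i <- if (is_clin && cf$beta != 0)
          .rtruncnorm0(1, cf$beta, cf$beta / 2) else 0
        noise_seed <- sample.int(2^31 - 1L, 1L)
        noise <- simulate_smooth_map(geometry, cf$smoothness_length_scale,
                                     seed = noise_seed, n_maps = 6L,
                                     factor = L) * cf$noise_sd
        field <- cf$gradient_loading * gradient +
          beta_i * signature + noise
        symptoms <- NULL
        if (is_clin) {
          symptoms <- c(
            positive = cf$symptom_coupling[["positive"]] * beta_i +
              rnorm(1, 0, cf$symptom_noise_sd),
            negative = cf$symptom_coupling[["negative"]] * beta_i +
              rnorm(1, 0, cf$symptom_noise_sd))
        }
        subjects[[sid]] <- list(
          subject_id = sprintf("S%03d", sid), group_label = g,
          maps = list(rest = mk_maps(field)),
          symptoms = symptoms, beta = beta_i)
      }
    }
    for (i in seq_len(cf$drug_group_size)) {
      sid <- sid + 1L
      noise_seed <- sample.int(2^31 - 1L, 1L)
      noise <- simulate_smooth_map(geometry, cf$smoothness_length_scale,
                                   seed = noise_seed, n_maps = 6L,
                                   factor = L) * cf$noise_sd
      base_field <- cf$gradient_loading * gradient + noise
      maps <- list(placebo = mk_maps(base_field))
      for (d in cf$drug_names) {
        beta_d <- .rtruncnorm0(1, cf$drug_beta, cf$drug_beta / 2)
        cond_noise_seed <- sample.int(2^31 - 1L, 1L)
        cond_noise <- simulate_smooth_map(
          geometry, cf$smoothness_length_scale, seed = cond_noise_seed,
          n_maps = 6L, factor = L) * cf$noise_sd * 0.5
        maps[[d]] <- mk_maps(base_field + beta_d * drug_patterns[[d]] +
                               cond_noise)
      }
      subjects[[sid]] <- list(
        subject_id = sprintf("S%03d", sid), group_label = "pharma",
        maps = maps, symptoms = NULL, beta = NA_real_)
    }
    subjects
  })
  structure(list(geometry = geometry, subjects = out,
                 truth = list(gradient = gradient, signature = signature,
                              drug_patterns = drug_patterns),
                 config = cf),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group_label"))
  cat(sprintf("<cohort> %d subjects (%s), %d parcels\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              n_parcels(x$geometry)))
  invisible(x)
}

#' Subjects of a cohort belonging to given groups
#' @param cohort a [simulate_cohort()] result.
#' @param groups character vector of group labels.
#' @export
cohort_subjects <- function(cohort, groups) {
  Filter(function(s) s$group_label %in% groups, cohort$subjects)
}

#' Geometry of homotopic-pair midpoints
#'
#' Reduces a bilateral geometry to one parcel per homotopic pair
#' (using the right-hemisphere member's coordinates), the support on
#' which hemisphere-averaged maps live.
#' @param geometry a bilateral [parcel_geometry()].
#' @export
half_geometry <- function(geometry) {
  hp <- geometry$homotopic_pairs
  if (is.null(hp)) stop_invalid("geometry has no homotopic pairing")
  idx <- hp$right
  parcel_geometry(seq_along(idx), geometry$sphere_xyz[idx, , drop = FALSE],
                  geometry$anat_xyz[idx, , drop = FALSE],
                  geometry$medial_wall[idx])
}

# Hemisphere-average every column of a parcels x parameters matrix
# (no-op for unilateral geometries).
collapse_hemispheres <- function(M, geometry) {
  if (is.null(geometry$homotopic_pairs)) return(M)
  apply(M, 2, average_hemispheres,
        homotopic_pairs = geometry$homotopic_pairs)
}

#' Group-level signature pattern matrix from a cohort
#'
#' The analysis path to a psychosis-signature pattern matrix: per
#' subject, hemisphere-average each parameter map (bilateral
#' geometries) and z-score it across parcels; then take, per
#' parameter, the mean clinical map minus the mean control map.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param clinical_groups,control_group group labels.
#' @param condition condition name (default `"rest"`).
#' @return list(X = parcels x 6 matrix, geometry = map support).
#' @export
signature_matrix <- function(cohort, clinical_groups = "clinical",
                             control_group = "control",
                             condition = "rest") {
  geom <- cohort$geometry
  half <- !is.null(geom$homotopic_pairs)
  get_z <- function(s) {
    M <- collapse_hemispheres(s$maps[[condition]], geom)
    apply(M, 2, zscore_map)
  }
  clin <- lapply(cohort_subjects(cohort, clinical_groups), get_z)
  ctrl <- lapply(cohort_subjects(cohort, control_group), get_z)
  if (!length(clin) || !length(ctrl))
    stop_invalid("empty clinical or control group")
  np <- nrow(clin[[1]])
  X <- vapply(seq_len(6L), function(p) {
    A <- t(vapply(clin, function(M) M[, p], numeric(np)))
    B <- t(vapply(ctrl, function(M) M[, p], numeric(np)))
    as.numeric(group_difference_map(A, B, mode = "mean_diff"))
  }, numeric(np))
  colnames(X) <- DYNAMICS_PARAMETERS
  list(X = X, geometry = if (half) half_geometry(geom) else geom)
}

#' Group-average drug-effect pattern matrix from a cohort
#'
#' Per parameter: z-score each pharmacology subject's
#' hemisphere-averaged drug and placebo maps and take the mean
#' within-subject difference ([drug_effect_map()]).
#'
#' @param cohort a [simulate_cohort()] result with pharmacology
#'   subjects.
#' @param drug drug condition name.
#' @return list(Y = parcels x 6 matrix, geometry = map support).
#' @export
drug_effect_matrix <- function(cohort, drug) {
  geom <- cohort$geometry
  subs <- cohort_subjects(cohort, "pharma")
  if (!length(subs)) stop_invalid("cohort has no pharmacology subjects")
  ids <- vapply(subs, `[[`, "", "subject_id")
  get_cond <- function(s, cond) collapse_hemispheres(s$maps[[cond]], geom)
  np <- nrow(get_cond(subs[[1]], "placebo"))
  Y <- vapply(seq_len(6L), function(p) {
    D <- t(vapply(subs, function(s) get_cond(s, drug)[, p], numeric(np)))
    P <- t(vapply(subs, function(s) get_cond(s, "placebo")[, p],
                  numeric(np)))
    rownames(D) <- rownames(P) <- ids
    as.numeric(drug_effect_map(D, P))
  }, numeric(np))
  colnames(Y) <- DYNAMICS_PARAMETERS
  half <- !is.null(geom$homotopic_pairs)
  list(Y = Y, geometry = if (half) half_geometry(geom) else geom)
}

#' Individual psychosis-signature vectors
#'
#' For each clinical subject: hemisphere-average and z-score each
#' parameter map, subtract the control group's mean (z-scored) map,
#' and concatenate the six parameter blocks vertically
#' ([concat_parameters_vertical()]).
#'
#' @inheritParams signature_matrix
#' @return matrix subjects x (6 * parcels), row names = subject ids.
#' @export
individual_signature_vectors <- function(cohort,
                                         clinical_groups = "clinical",
                                         control_group = "control",
                                         condition = "rest") {
  geom <- cohort$geometry
  get_z <- function(s) {
    M <- collapse_hemispheres(s$maps[[condition]], geom)
    apply(M, 2, zscore_map)
  }
  ctrl <- lapply(cohort_subjects(cohort, control_group), get_z)
  if (!length(ctrl)) stop_invalid("empty control group")
  ctrl_mean <- Reduce(`+`, ctrl) / length(ctrl)
  clin <- cohort_subjects(cohort, clinical_groups)
  if (!length(clin)) stop_invalid("empty clinical group")
  out <- t(vapply(clin, function(s) {
    M <- get_z(s) - ctrl_mean
    concat_parameters_vertical(
      setNames(lapply(seq_len(6L), function(p) M[, p]),
               DYNAMICS_PARAMETERS))
  }, numeric(6L * nrow(ctrl_mean))))
  rownames(out) <- vapply(clin, `[[`, "", "subject_id")
  out
}

#' Symptom-score table of a cohort
#' @inheritParams signature_matrix
#' @export
cohort_symptoms <- function(cohort, clinical_groups = "clinical") {
  subs <- cohort_subjects(cohort, clinical_groups)
  data.frame(
    subject_id = vapply(subs, `[[`, "", "subject_id"),
    positive = vapply(subs, function(s) s$symptoms[["positive"]],
                      numeric(1)),
    negative = vapply(subs, function(s) s$symptoms[["negative"]],
                      numeric(1)))
}
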