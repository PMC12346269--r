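#' Six-parameter feature table from parcel time series
#'
#' The full per-parcel extraction pipeline: Welch PSD (0.1 Hz grid),
#' power-line interpolation, aperiodic + peak model fit (knee model
#' with fixed-mode fallback), constrained alpha extraction against a
#' visual-reference mean PSD, aperiodic AUC, and DFA Hurst exponent of
#' the alpha-band amplitude envelope (filter transients of
#' `2 * fir_order` samples trimmed before DFA).
#'
#' @param timeseries list of numeric vectors (or a parcels x samples
#'   matrix), one per parcel.
#' @param fs sampling rate, Hz.
#' @param reference_parcels indices of the visual reference parcels
#'   used to constrain the alpha search (see [extract_alpha()]).
#' @param fit_range spectral fit range, Hz.
#' @param line_freqs power-line frequencies to interpolate (those above
#'   the spectrum's support are skipped).
#' @param epoch_seconds Welch epoch length, s.
#' @param dfa_args list of overrides passed to [dfa_hurst()].
#' @param fir_order FIR order of the alpha-band filter.
#' @return data.frame: parcel_id plus the six [DYNAMICS_PARAMETERS].
#' @export
parcel_feature_table <- function(timeseries, fs, reference_parcels,
                                 fit_range = c(1, 65),
                                 line_freqs = c(50, 100, 150),
                                 epoch_seconds = 10,
                                 dfa_args = list(),
                                 fir_order = 100L) {
  if (is.matrix(timeseries))
    timeseries <- lapply(seq_len(nrow(timeseries)),
                         function(i) timeseries[i, ])
  np <- length(timeseries)
  if (!length(reference_parcels) ||
      any(reference_parcels < 1L | reference_parcels > np))
    stop_invalid("reference_parcels must index the parcel list")
  psds <- lapply(timeseries, function(x) {
    s <- welch_psd(x, fs, epoch_seconds = epoch_seconds)
    interpolate_line_noise(s, line_freqs = line_freqs[
      line_freqs - 2 <= max(s$freqs)])
  })
  fits <- lapply(psds, fit_spectral_model, fit_range = fit_range)
  ref_psd <- power_spectrum(psds[[1]]$freqs,
                            Reduce(`+`, lapply(psds[reference_parcels],
                                               `[[`, "power")) /
                              length(reference_parcels))
  alpha <- extract_alpha(lapply(fits, `[[`, "peaks"), ref_psd,
                         fit_range = fit_range)
  hurst <- vapply(timeseries, function(x) {
    env <- alpha_envelope(x, fs, fir_order = fir_order)
    trim <- 2L * fir_order
    env <- env[(trim + 1L):(length(env) - trim)]
    do.call(dfa_hurst, c(list(envelope = env, fs = fs), dfa_args))$hurst
  }, numeric(1))
  ap <- lapply(fits, summarize_spectrum)
  data.frame(
    parcel_id = seq_len(np),
    exponent = vapply(fits, function(f) f$aperiodic$exponent, numeric(1)),
    knee_frequency = vapply(ap, `[[`, numeric(1), "knee_frequency"),
    auc = vapply(ap, `[[`, numeric(1), "auc"),
    hurst = hurst,
    alpha_power = alpha$alpha_power,
    alpha_frequency = alpha$alpha_frequency)
}

#' Per-parcel time-series parameters from a subject's parameter maps
#'
#' Inverts the natural-unit parameter maps of a synthetic subject into
#' [timeseries_params()] for each parcel: exponent and Hurst map
#' directly, the knee parameter is `knee_frequency^exponent`, the
#' offset is solved so that the summed aperiodic power over 1-65 Hz
#' equals the subject's AUC value, and alpha power/frequency set the
#' oscillation. Values are clamped to physically admissible ranges.
#'
#' @param maps `n_parcels x 6` matrix (columns [DYNAMICS_PARAMETERS]).
#' @param alpha_bandwidth spectral bandwidth of the alpha peak, Hz.
#' @return list of [timeseries_params()], one per parcel.
#' @export
maps_to_timeseries_params <- function(maps, alpha_bandwidth = 4) {
  M <- as.matrix(maps)
  lapply(seq_len(nrow(M)), function(i) {
    chi <- min(max(M[i, "exponent"], 0.3), 6)
    fk <- max(M[i, "knee_frequency"], 0.5)
    k <- fk^chi
    f <- seq(1, 65, by = 0.1)
    b <- log10(max(M[i, "auc"], 1e-6) / sum(1 / (k + f^chi)))
    timeseries_params(
      offset = b, knee = k, exponent = chi,
      alpha_frequency = min(max(M[i, "alpha_frequency"], 6), 14),
      alpha_amplitude = max(M[i, "alpha_power"], 0),
      alpha_bandwidth = alpha_bandwidth,
      hurst = min(max(M[i, "hurst"], 0.1), 1.4))
  })
}

#' Emit a synthetic subject as per-parcel time series
#'
#' @param cohort a [simulate_cohort()] result.
#' @param subject_id subject identifier.
#' @param condition condition name.
#' @param fs,duration sampling rate (Hz) and record length (s);
#'   defaults from the cohort config.
#' @param seed integer seed (parcel seeds derive from it).
#' @return list of numeric vectors, one per parcel.
#' @export
simulate_subject_timeseries <- function(cohort, subject_id,
                                        condition = "rest",
                                        fs = NULL, duration = NULL,
                                        seed = 1L) {
  subj <- Filter(function(s) s$subject_id == subject_id,
                 cohort$subjects)
  if (!length(subj)) stop_invalid("unknown subject_id")
  subj <- subj[[1]]
  ts_cf <- cohort$config$timeseries
  fs <- fs %||% ts_cf$fs
  duration <- duration %||% ts_cf$duration
  plist <- maps_to_timeseries_params(subj$maps[[condition]],
                                     alpha_bandwidth =
                                       ts_cf$alpha_bandwidth %||% 4)
  lapply(seq_along(plist), function(i)
    simulate_parcel_timeseries(plist[[i]], fs = fs, duration = duration,
                               seed = seed + 131L * i))
}
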