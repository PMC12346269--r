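#' Parameterize a power spectrum into aperiodic and periodic parts
#'
#' Fits, in log10-power space, the aperiodic model with knee
#' \deqn{L(f) = b - \log_{10}(k + f^{\chi})}
#' plus Gaussian peaks on the residual (height above the aperiodic
#' component, detected iteratively above `peak_threshold_sd` residual
#' standard deviations, bandwidths constrained to
#' `peak_width_limits`). If the knee fit fails to converge or the knee
#' parameter collapses to (or below) zero, the model is refit with the
#' knee fixed at 0 and `mode = "fixed"`; the knee frequency is then
#' reported as missing. Knee frequency is the standard conversion
#' \eqn{f_k = k^{1/\chi}}.
#'
#' @param spectrum a [power_spectrum()].
#' @param fit_range frequency range (Hz) of the fit, default 1-65 Hz.
#' @param peak_threshold_sd peak detection threshold in residual SDs.
#' @param peak_width_limits bandwidth (2 SD of the Gaussian) limits, Hz.
#' @param knee logical; start with the knee model (default TRUE).
#' @param max_n_peaks maximum number of Gaussian peaks.
#' @param min_peak_height absolute floor (log10 units) below which
#'   detected peaks are discarded; guards against numerically
#'   degenerate "peaks" on near-noiseless spectra.
#' @return A `spectral_fit`: list with `aperiodic` (offset, knee,
#'   exponent, mode, knee_frequency), `peaks` (data.frame
#'   center_frequency / peak_power / bandwidth), `freqs`, `fitted`
#'   (log10 model), `r_squared`.
#' @export
fit_spectral_model <- function(spectrum, fit_range = c(1, 65),
                               peak_threshold_sd = 2,
                               peak_width_limits = c(2, 16),
                               knee = TRUE, max_n_peaks = 6L,
                               min_peak_height = 0.01) {
  sel <- spectrum$freqs >= fit_range[1] & spectrum$freqs <= fit_range[2]
  f <- spectrum$freqs[sel]
  p <- spectrum$power[sel]
  if (length(f) < 8L) stop_invalid("too few bins inside fit_range")
  if (any(p <= 0))
    stop_invalid("non-positive power inside fit_range; cannot take log10")
  lp <- log10(p)

  fit <- .spectral_fit_once(f, lp, knee = knee,
                            peak_threshold_sd = peak_threshold_sd,
                            sigma_limits = peak_width_limits / 2,
                            max_n_peaks = max_n_peaks,
                            min_peak_height = min_peak_height)
  # fallback: optimizer failure, or a knee frequency below the fitted
  # range (with the box constraint k >= 0, a spurious/negative knee
  # collapses toward the boundary rather than going negative)
  if (knee && (!fit$converged ||
               fit$ap[2]^(1 / fit$ap[3]) < fit_range[1])) {
    fit <- .spectral_fit_once(f, lp, knee = FALSE,
                              peak_threshold_sd = peak_threshold_sd,
                              sigma_limits = peak_width_limits / 2,
                              max_n_peaks = max_n_peaks,
                              min_peak_height = min_peak_height)
    mode <- "fixed"
  } else {
    mode <- if (knee) "with_knee" else "fixed"
  }
  ap <- fit$ap
  knee_frequency <- if (mode == "with_knee") unname(ap[2]^(1 / ap[3])) else NA_real_
  fitted_lp <- .ap_model(ap, f) + .gauss_model(fit$peaks, f)
  structure(list(
    aperiodic = list(offset = unname(ap[1]),
                     knee = if (mode == "with_knee") unname(ap[2]) else 0,
                     exponent = unname(ap[3]),
                     mode = mode,
                     knee_frequency = knee_frequency),
    peaks = fit$peaks,
    freqs = f,
    fitted = fitted_lp,
    r_squared = 1 - sum((lp - fitted_lp)^2) / sum((lp - mean(lp))^2)),
    class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  a <- x$aperiodic
  cat(sprintf(
    "<spectral_fit> mode=%s exponent=%.3f knee_freq=%s offset=%.3f, %d peak(s), R2=%.3f\n",
    a$mode, a$exponent,
    if (is.na(a$knee_frequency)) "NA" else sprintf("%.2f Hz", a$knee_frequency),
    a$offset, nrow(x$peaks), x$r_squared))
  invisible(x)
}

# log10 aperiodic model; ap = c(offset b, knee k, exponent chi)
.ap_model <- function(ap, f) ap[1] - log10(ap[2] + f^ap[3])

.gauss_model <- function(peaks, f) {
  y <- numeric(length(f))
  if (is.null(peaks) || !nrow(peaks)) return(y)
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$bandwidth[i] / 2
    y <- y + peaks$peak_power[i] *
      exp(-(f - peaks$center_frequency[i])^2 / (2 * s^2))
  }
  y
}

# One full fit pass: robust aperiodic -> peak detection -> joint
# Gaussian fit -> aperiodic refit on flattened spectrum -> Gaussian
# refit -> spurious-peak filter.
.spectral_fit_once <- function(f, lp, knee, peak_threshold_sd,
                               sigma_limits, max_n_peaks,
                               min_peak_height = 0.01) {
  ap0 <- .fit_aperiodic(f, lp, knee = knee)
  # robust refit: drop bins sitting above the curve (candidate peaks)
  flat <- lp - .ap_model(ap0$par, f)
  flat_pos <- pmax(flat, 0)
  keep <- flat <= max(0, quantile(flat_pos, 0.025))
  ap1 <- if (sum(keep) >= 8L)
    .fit_aperiodic(f[keep], lp[keep], knee = knee, init = ap0$par)
  else ap0

  resid <- lp - .ap_model(ap1$par, f)
  guesses <- .detect_peaks(f, resid, peak_threshold_sd, sigma_limits,
                           max_n_peaks, min_peak_height)
  guesses <- .drop_overlapping_peaks(guesses)
  peaks <- .fit_gaussians(f, resid, guesses, sigma_limits)
  peaks <- .drop_overlapping_peaks(peaks)

  ap2 <- .fit_aperiodic(f, lp - .gauss_model(peaks, f), knee = knee,
                        init = ap1$par)
  resid2 <- lp - .ap_model(ap2$par, f)
  peaks <- .fit_gaussians(f, resid2, peaks, sigma_limits)
  peaks <- .drop_overlapping_peaks(peaks)

  # drop peaks indistinguishable from residual noise or hugging the edge
  if (nrow(peaks)) {
    final_resid <- resid2 - .gauss_model(peaks, f)
    noise_sd <- stats::mad(final_resid)
    ok <- peaks$peak_power >= max(peak_threshold_sd * noise_sd,
                                  min_peak_height) &
      peaks$center_frequency > f[1] + 0.5 &
      peaks$center_frequency < f[length(f)] - 0.5
    peaks <- peaks[ok, , drop = FALSE]
  }
  list(ap = ap2$par, peaks = peaks,
       converged = ap0$converged && ap1$converged && ap2$converged)
}

# Least-squares aperiodic fit in log10 space via L-BFGS-B multistart.
.fit_aperiodic <- function(f, lp, knee, init = NULL) {
  logf <- log10(f)
  slope <- -(lp[length(lp)] - lp[1]) / (logf[length(logf)] - logf[1])
  chi0 <- min(max(slope, 0.1), 8)
  obj <- function(par) {
    r <- lp - .ap_model(par, f)
    sum(r * r)
  }
  grad <- function(par) {
    den <- par[2] + f^par[3]
    r <- lp - (par[1] - log10(den))
    g_b <- sum(r)
    g_k <- -sum(r / den) / log(10)
    g_chi <- -sum(r * f^par[3] * log(f) / den) / log(10)
    -2 * c(g_b, g_k, g_chi)
  }
  lower <- c(-Inf, 0, 0.01)
  upper <- c(Inf, if (knee) 1e7 else 0, 10)
  starts <- list()
  if (!is.null(init)) {
    init[2] <- min(max(init[2], lower[2]), upper[2])
    init[3] <- min(max(init[3], lower[3]), upper[3])
    starts <- list(init)
  }
  if (knee) {
    for (fk in c(0, 2, 8, 25)) {
      k0 <- fk^chi0
      b0 <- lp[1] + log10(k0 + f[1]^chi0)
      starts <- c(starts, list(c(b0, k0, chi0)))
    }
  } else {
    starts <- c(starts, list(c(lp[1] + chi0 * logf[1], 0, chi0)))
  }
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, obj, gr = grad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(list(par = starts[[length(starts)]], converged = FALSE))
  list(par = best$par, converged = best$convergence == 0)
}

# Iterative peak detection on the flattened (residual) spectrum.
.detect_peaks <- function(f, resid, threshold_sd, sigma_limits,
                          max_n_peaks, min_peak_height = 0.01) {
  df <- f[2] - f[1]
  out <- data.frame(center_frequency = numeric(0),
                    peak_power = numeric(0), bandwidth = numeric(0))
  r <- resid
  for (it in seq_len(max_n_peaks)) {
    i <- which.max(r)
    h <- r[i]
    if (!is.finite(h) || h < max(threshold_sd * sd(r), min_peak_height))
      break
    # half-height width estimate
    half <- h / 2
    li <- i; while (li > 1 && r[li] > half) li <- li - 1
    ri <- i; while (ri < length(r) && r[ri] > half) ri <- ri + 1
    fwhm <- max(df, (f[ri] - f[li]))
    sig <- min(max(fwhm / 2.355, sigma_limits[1]), sigma_limits[2])
    out <- rbind(out, data.frame(center_frequency = f[i],
                                 peak_power = h, bandwidth = 2 * sig))
    r <- r - h * exp(-(f - f[i])^2 / (2 * sig^2))
  }
  out
}

# Greedy overlap resolution: keep peaks in decreasing power order,
# dropping any whose center lies within 1.5 SD of an already-kept peak
# (either peak's SD). Prevents one broad peak being modeled as two.
.drop_overlapping_peaks <- function(peaks) {
  if (is.null(peaks) || nrow(peaks) < 2L) return(peaks)
  ord <- order(-peaks$peak_power)
  kept <- integer(0)
  for (i in ord) {
    si <- peaks$bandwidth[i] / 2
    clash <- FALSE
    for (j in kept) {
      sj <- peaks$bandwidth[j] / 2
      if (abs(peaks$center_frequency[i] - peaks$center_frequency[j]) <
          1.5 * max(si, sj)) { clash <- TRUE; break }
    }
    if (!clash) kept <- c(kept, i)
  }
  peaks[sort(kept), , drop = FALSE]
}

# Joint least-squares refinement of all Gaussians.
.fit_gaussians <- function(f, resid, guesses, sigma_limits) {
  if (is.null(guesses) || !nrow(guesses)) return(
    data.frame(center_frequency = numeric(0), peak_power = numeric(0),
               bandwidth = numeric(0)))
  np <- nrow(guesses)
  par0 <- as.numeric(t(as.matrix(
    guesses[, c("center_frequency", "peak_power", "bandwidth")])))
  par0[seq(3, length(par0), by = 3)] <- par0[seq(3, length(par0), by = 3)] / 2
  lower <- numeric(0); upper <- numeric(0)
  for (i in seq_len(np)) {
    cf <- guesses$center_frequency[i]
    sg <- guesses$bandwidth[i] / 2
    lower <- c(lower, cf - 1.5 * sg, 0, sigma_limits[1])
    upper <- c(upper, cf + 1.5 * sg, Inf, sigma_limits[2])
  }
  model <- function(par) {
    y <- numeric(length(f))
    for (i in seq_len(np)) {
      cf <- par[3 * i - 2]; h <- par[3 * i - 1]; s <- par[3 * i]
      y <- y + h * exp(-(f - cf)^2 / (2 * s^2))
    }
    y
  }
  obj <- function(par) sum((resid - model(par))^2)
  grad <- function(par) {
    r <- resid - model(par)
    g <- numeric(length(par))
    for (i in seq_len(np)) {
      cf <- par[3 * i - 2]; h <- par[3 * i - 1]; s <- par[3 * i]
      e <- exp(-(f - cf)^2 / (2 * s^2))
      g[3 * i - 2] <- -2 * sum(r * h * e * (f - cf) / s^2)
      g[3 * i - 1] <- -2 * sum(r * e)
      g[3 * i] <- -2 * sum(r * h * e * (f - cf)^2 / s^3)
    }
    g
  }
  res <- tryCatch(
    optim(par0, obj, gr = grad, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = 300)),
    error = function(e) list(par = par0))
  p <- res$par
  data.frame(center_frequency = p[seq(1, 3 * np, 3)],
             peak_power = p[seq(2, 3 * np, 3)],
             bandwidth = 2 * p[seq(3, 3 * np, 3)])
}

#' Aperiodic-fit summaries: AUC and knee frequency
#'
#' The AUC is the summed modeled aperiodic power (linear units) on the
#' 0.1 Hz grid between 1 and 65 Hz — a proxy of overall population
#' activity. The knee frequency is \eqn{k^{1/\chi}} when the knee model
#' was fitted, otherwise missing.
#'
#' @param fit a `spectral_fit` (or its `$aperiodic` element).
#' @param auc_range summation range in Hz.
#' @param grid_step summation grid step in Hz.
#' @return list with `auc` and `knee_frequency`.
#' @export
summarize_spectrum <- function(fit, auc_range = c(1, 65), grid_step = 0.1) {
  a <- if (inherits(fit, "spectral_fit")) fit$aperiodic else fit
  stopifnot(is.list(a), !is.null(a$exponent))
  f <- seq(auc_range[1], auc_range[2], by = grid_step)
  k <- if (identical(a$mode, "with_knee")) a$knee else 0
  auc <- sum(10^a$offset / (k + f^a$exponent))
  list(auc = auc,
       knee_frequency = if (identical(a$mode, "with_knee"))
         a$knee_frequency else NA_real_)
}

#' Constrained alpha-peak extraction across parcels
#'
#' Mirrors the two-stage procedure used for MEG parcels: (i) fit the
#' spectral model to the mean PSD over a set of visual reference
#' parcels (where alpha is strongest) and take its alpha peak (7-13 Hz;
#' if several, the highest); (ii) in every parcel, restrict candidate
#' peaks to the reference peak's band (center +/- bandwidth/2) widened
#' by `search_pad` Hz on each side; (iii) among multiple candidates
#' keep the one with the highest power; (iv) if the reference has no
#' alpha peak, fall back to each parcel's highest-power peak within
#' 7-13 Hz; (v) with no candidate at all, alpha power and frequency
#' are missing.
#'
#' @param peaks_per_parcel list of per-parcel peak data.frames (as in
#'   `spectral_fit$peaks`).
#' @param reference_psd mean [power_spectrum()] across the visual
#'   reference parcels, or a ready `spectral_fit` of it.
#' @param search_pad widening of the reference band, Hz.
#' @param alpha_range admissible range for the reference peak, Hz.
#' @param ... passed to [fit_spectral_model()] for the reference fit.
#' @return data.frame with one row per parcel: `alpha_frequency`,
#'   `alpha_power` (NA when missing); attribute `window` holds the
#'   search window used (NULL when in fallback mode).
#' @export
extract_alpha <- function(peaks_per_parcel, reference_psd, search_pad = 2,
                          alpha_range = c(7, 13), ...) {
  if (is.null(reference_psd))
    stop_invalid("empty visual reference: reference_psd is required")
  ref_fit <- if (inherits(reference_psd, "spectral_fit")) reference_psd
             else fit_spectral_model(reference_psd, ...)
  rp <- ref_fit$peaks
  rp <- rp[rp$center_frequency >= alpha_range[1] &
             rp$center_frequency <= alpha_range[2], , drop = FALSE]
  window <- NULL
  if (nrow(rp)) {
    rp <- rp[which.max(rp$peak_power), ]
    window <- c(rp$center_frequency - rp$bandwidth / 2 - search_pad,
                rp$center_frequency + rp$bandwidth / 2 + search_pad)
  }
  pick <- function(peaks) {
    if (is.null(peaks) || !nrow(peaks))
      return(c(NA_real_, NA_real_))
    rng <- window %||% alpha_range
    cand <- peaks[peaks$center_frequency >= rng[1] &
                    peaks$center_frequency <= rng[2], , drop = FALSE]
    if (!nrow(cand)) return(c(NA_real_, NA_real_))
    best <- cand[which.max(cand$peak_power), ]
    c(best$center_frequency, best$peak_power)
  }
  res <- t(vapply(peaks_per_parcel, pick, numeric(2)))
  out <- data.frame(alpha_frequency = res[, 1], alpha_power = res[, 2])
  attr(out, "window") <- window
  out
}
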