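#' Welch power spectral density on a 0.1 Hz grid
#'
#' Splits a parcel time series into `epoch_seconds`-long epochs with
#' `overlap_fraction` overlap, Hann-tapers and Fourier-transforms each
#' epoch, and averages across epochs. With the default 10-s epochs the
#' frequency resolution is 0.1 Hz. The default magnitude convention is
#' power (averaged squared magnitudes, one-sided density in
#' units^2/Hz); `magnitude = "amplitude"` averages absolute Fourier
#' coefficients instead (which halves the scale of any fitted aperiodic
#' exponent).
#'
#' @param timeseries numeric vector.
#' @param fs sampling rate (Hz); `fs * epoch_seconds` must be integer.
#' @param epoch_seconds epoch length in seconds.
#' @param overlap_fraction fractional overlap between epochs.
#' @param magnitude `"power"` (default) or `"amplitude"`.
#' @return A `power_spectrum`: list with `freqs` (Hz) and `power`,
#'   plus attributes `n_epochs`, `fs`.
#' @export
welch_psd <- function(timeseries, fs, epoch_seconds = 10,
                      overlap_fraction = 0.5,
                      magnitude = c("power", "amplitude")) {
  magnitude <- match.arg(magnitude)
  x <- as.numeric(timeseries)
  nper <- fs * epoch_seconds
  if (abs(nper - round(nper)) > 1e-9)
    stop_invalid("fs * epoch_seconds must be an integer number of samples")
  nper <- as.integer(round(nper))
  if (length(x) < nper)
    stop_invalid("time series too short: need at least ", nper,
                 " samples (one ", epoch_seconds, "-s epoch), got ",
                 length(x))
  step <- max(1L, as.integer(round(nper * (1 - overlap_fraction))))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- hann_window(nper)
  scale_pow <- 1 / (fs * sum(w^2))
  nf <- nper %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf + 1L)]
    if (magnitude == "power") {
      acc <- acc + Mod(X)^2
    } else {
      acc <- acc + Mod(X)
    }
  }
  acc <- acc / length(starts)
  if (magnitude == "power") {
    p <- acc * scale_pow
    p[c(-1L, -(nf + 1L))] <- 2 * p[c(-1L, -(nf + 1L))]
  } else {
    # averaged |coefficients|, scaled to an amplitude density
    p <- acc * sqrt(scale_pow)
    p[c(-1L, -(nf + 1L))] <- sqrt(2) * p[c(-1L, -(nf + 1L))]
  }
  power_spectrum(seq(0, nf) / epoch_seconds, p,
                 n_epochs = length(starts), fs = fs)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)

#' Construct a power spectrum object
#' @param freqs strictly increasing frequency grid (Hz).
#' @param power nonnegative power values.
#' @param ... extra attributes (e.g. `n_epochs`).
#' @export
power_spectrum <- function(freqs, power, ...) {
  if (length(freqs) != length(power))
    stop_invalid("freqs and power lengths differ")
  if (any(diff(freqs) <= 0)) stop_invalid("freqs must be strictly increasing")
  if (any(power < 0)) stop_invalid("power must be nonnegative")
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power), ...),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.2f-%.2f Hz (step %.3g Hz)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              stats::median(diff(x$freqs))))
  invisible(x)
}

#' Interpolate power-line noise bands out of a spectrum
#'
#' Replaces power inside `line_freqs` +/- `halfwidth` by the straight
#' line joining the band-edge values; all bins strictly outside the
#' bands are returned bit-identical. Idempotent.
#'
#' @param spectrum a `power_spectrum`.
#' @param line_freqs line frequencies (Hz); bands above the spectrum's
#'   support are skipped, bands partially covered raise an error.
#' @param halfwidth half-width of each interpolated band (Hz).
#' @export
interpolate_line_noise <- function(spectrum, line_freqs = c(50, 100, 150),
                                   halfwidth = 2) {
  f <- spectrum$freqs
  p <- spectrum$power
  for (lf in line_freqs) {
    if (lf - halfwidth > max(f)) next   # band entirely above support
    lo <- lf - halfwidth
    hi <- lf + halfwidth
    if (lo < min(f) || hi > max(f))
      stop_invalid("line-noise band ", lo, "-", hi,
                   " Hz exceeds spectrum support")
    inner <- which(f > lo & f < hi)
    if (!length(inner)) next
    i_lo <- max(which(f <= lo))
    i_hi <- min(which(f >= hi))
    p[inner] <- approx(x = f[c(i_lo, i_hi)], y = p[c(i_lo, i_hi)],
                       xout = f[inner])$y
  }
  out <- spectrum
  out$power <- p
  out
}
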