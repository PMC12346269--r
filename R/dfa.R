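#' Alpha-band amplitude envelope
#'
#' Band-pass filters the signal with a zero-phase order-`fir_order`
#' windowed-sinc (Hamming) FIR filter and returns the amplitude
#' envelope as the modulus of the analytic signal (FFT Hilbert
#' transform). Output length equals input length; the first and last
#' ~`fir_order` samples carry filter ring-in and are trimmed by the
#' feature pipeline before DFA.
#'
#' @param timeseries numeric vector.
#' @param fs sampling rate, Hz (must exceed twice the upper band edge).
#' @param band passband in Hz, default alpha 8-13.
#' @param fir_order FIR filter order (number of taps minus one).
#' @return numeric envelope, same length as input.
#' @export
alpha_envelope <- function(timeseries, fs, band = c(8, 13),
                           fir_order = 100L) {
  x <- as.numeric(timeseries)
  if (fs <= 2 * band[2])
    stop_invalid("fs must exceed twice the upper band edge")
  if (length(x) <= 3L * fir_order)
    stop_invalid("time series too short: need > ", 3L * fir_order,
                 " samples for an order-", fir_order, " filter")
  h <- fir_bandpass(fir_order, band, fs)
  y <- fir_filtfilt_zero_phase(x, h)
  Mod(analytic_signal(y))
}

# Linear-phase windowed-sinc band-pass (Hamming window), odd tap count.
fir_bandpass <- function(order, band, fs) {
  n <- order + 1L
  m <- seq(0, order) - order / 2
  sinc <- function(z) ifelse(z == 0, 1, sin(pi * z) / (pi * z))
  f1 <- band[1] / (fs / 2); f2 <- band[2] / (fs / 2)
  h <- f2 * sinc(f2 * m) - f1 * sinc(f1 * m)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, order) / order)
  h <- h * w
  # unit mean gain over the central half of the passband (compensates
  # the windowed-sinc passband droop)
  bw <- band[2] - band[1]
  fg <- seq(band[1] + bw / 4, band[2] - bw / 4, length.out = 25) / (fs / 2)
  gain <- vapply(fg, function(fc)
    abs(sum(h * exp(-1i * pi * fc * seq(0, order)))), numeric(1))
  h / mean(gain)
}

# Zero-phase filtering: symmetric centered FIR applied by FFT
# convolution with zero padding, trimmed back to the input support.
fir_filtfilt_zero_phase <- function(x, h) {
  n <- length(x); nh <- length(h)
  half <- (nh - 1L) %/% 2L
  nfft <- .next_pow2(n + nh)
  X <- fft(c(x, numeric(nfft - n)))
  H <- fft(c(h, numeric(nfft - nh)))
  y <- Re(fft(X * H, inverse = TRUE)) / nfft
  y[(half + 1L):(half + n)]
}

# Analytic signal via frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[c(1, n / 2 + 1)] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[1] <- 1
    mult[2:((n + 1) / 2)] <- 2
  }
  fft(X * mult, inverse = TRUE) / n
}

#' Detrended fluctuation analysis of an amplitude envelope
#'
#' Cumulatively sums the mean-removed envelope, splits the profile into
#' 50%-overlapping windows at `n_window_sizes` log-spaced sizes within
#' `window_range`, removes a linear trend per window, and takes the RMS
#' residual per window size. The Hurst exponent is the log-log slope of
#' fluctuation versus window size over `fit_range`.
#'
#' @param envelope numeric vector (amplitude envelope).
#' @param fs sampling rate, Hz.
#' @param window_range calculation range of window sizes, seconds.
#' @param overlap fractional window overlap.
#' @param fit_range range of window sizes used for the slope, seconds.
#' @param n_window_sizes number of log-spaced window sizes.
#' @return A `dfa_result`: list with `hurst`, `window_sizes` (s),
#'   `fluctuation`, `fit_range`.
#' @export
dfa_hurst <- function(envelope, fs, window_range = c(1, 120),
                      overlap = 0.5, fit_range = c(3, 50),
                      n_window_sizes = 20L) {
  x <- as.numeric(envelope)
  n <- length(x)
  if (n < 2 * fit_range[2] * fs)
    stop_invalid("envelope too short: need at least 2 x ", fit_range[2],
                 " s (", 2 * fit_range[2] * fs, " samples)")
  wmax <- min(window_range[2], n / fs)
  sizes_s <- 10^seq(log10(window_range[1]), log10(wmax),
                    length.out = n_window_sizes)
  sizes <- unique(pmax(4L, as.integer(round(sizes_s * fs))))
  sizes <- sizes[sizes <= n]
  prof <- cumsum(x - mean(x))
  fluct <- vapply(sizes, function(s) {
    step <- max(1L, as.integer(floor(s * (1 - overlap))))
    starts <- seq(1L, n - s + 1L, by = step)
    idx <- outer(0:(s - 1L), starts, `+`)
    W <- matrix(prof[idx], nrow = s)
    t <- seq_len(s)
    X <- cbind(1, t)
    res <- W - X %*% solve(crossprod(X), crossprod(X, W))
    sqrt(mean(res^2))
  }, numeric(1))
  sizes_sec <- sizes / fs
  in_fit <- sizes_sec >= fit_range[1] & sizes_sec <= fit_range[2]
  if (sum(in_fit) < 3L)
    stop_invalid("fewer than 3 window sizes inside fit_range")
  co <- stats::coef(lm(log10(fluct[in_fit]) ~ log10(sizes_sec[in_fit])))
  structure(list(hurst = unname(co[2]), window_sizes = sizes_sec,
                 fluctuation = fluct, fit_range = fit_range),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> H = %.3f over %d window sizes (fit %g-%g s)\n",
              x$hurst, length(x$window_sizes),
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}
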