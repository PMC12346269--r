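#' Simulate fractional Gaussian noise (Davies–Harte)
#'
#' Exact simulation of fractional Gaussian noise with Hurst exponent
#' `H` by circulant embedding of the autocovariance
#' \eqn{\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})}.
#' Used both as the long-range-correlated envelope driver of the
#' synthetic time-series generator and as the independent oracle for
#' DFA recovery tests.
#'
#' @param n number of samples.
#' @param H Hurst exponent in (0, 1).
#' @param seed integer seed.
#' @return numeric vector of length `n`, unit-variance fGn.
#' @export
fgn_sim <- function(n, H, seed) {
  if (!is.numeric(H) || H <= 0 || H >= 1)
    stop_invalid("H must be in (0, 1)")
  n <- as.integer(n)
  if (H == 0.5) return(with_seed(seed, rnorm(n)))
  m <- 2L * .next_pow2(n)
  k <- 0:(m / 2)
  gamma <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                    abs(k - 1)^(2 * H))
  row <- c(gamma, gamma[(m / 2):2])          # circulant first row
  lambda <- Re(fft(row))
  # tiny negative eigenvalues can appear from roundoff; clamp
  lambda <- pmax(lambda, 0)
  z <- with_seed(seed, {
    complex(real = rnorm(m), imaginary = rnorm(m))
  })
  # iid complex spectrum + real part halves the power; the sqrt(1/m)
  # (not 1/(2m)) scaling restores unit variance
  w <- fft(sqrt(lambda / m) * z)
  Re(w)[seq_len(n)]
}

#' Long-range-correlated noise covering H in (0, 1.5)
#'
#' For `H < 1` returns fGn; for `H >= 1` returns the cumulative sum of
#' fGn with Hurst `H - 1` (rescaled to unit variance), whose DFA
#' scaling exponent is `H`.
#'
#' @inheritParams fgn_sim
#' @param H target DFA scaling exponent in (0, 1.5).
#' @export
lrc_noise <- function(n, H, seed) {
  if (!is.numeric(H) || H <= 0 || H >= 1.5)
    stop_invalid("H must be in (0, 1.5)")
  if (H < 1) return(fgn_sim(n, H, seed))
  x <- cumsum(fgn_sim(n, H - 1, seed))
  as.numeric(scale(x))
}

.next_pow2 <- function(n) 2L^ceiling(log2(max(2L, n)))
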