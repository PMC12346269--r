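# Shared fixtures, all generated in code.

# Small unilateral geometry cached per session
small_geom <- local({
  cache <- NULL
  function(n = 60, seed = 1) {
    key <- paste(n, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- make_geometry(n, seed = seed)
    cache[[key]]
  }
})

# Spectrum generated exactly from the aperiodic + Gaussian-peak model
model_spectrum <- function(b = 1, k = 100, chi = 2,
                           peaks = data.frame(cf = 10, h = 0.8, bw = 4),
                           freqs = seq(0.1, 80, by = 0.1),
                           noise_sd = 0, seed = 1) {
  lp <- b - log10(k + freqs^chi)
  if (!is.null(peaks) && nrow(peaks)) {
    for (i in seq_len(nrow(peaks)))
      lp <- lp + peaks$h[i] *
        exp(-(freqs - peaks$cf[i])^2 / (2 * (peaks$bw[i] / 2)^2))
  }
  if (noise_sd > 0)
    lp <- lp + withr::with_seed(seed, rnorm(length(freqs), 0, noise_sd))
  power_spectrum(freqs, 10^lp)
}

# Ring-lattice weight matrix with 2 neighbours (Moran's I closed form)
ring_weights <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, (i %% n) + 1] <- 1
    W[i, ((i - 2) %% n) + 1] <- 1
  }
  W
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
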