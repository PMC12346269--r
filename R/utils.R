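#' @importFrom stats cor fft lm median optim pf prcomp quantile rnorm runif sd var approx anova coef setNames complete.cases
#' @importFrom utils head tail
NULL

# Evaluate expr with a local, restored RNG state seeded at `seed`.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
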