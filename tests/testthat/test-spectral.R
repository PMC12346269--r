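test_that("welch_psd: tone location, epoch count, flat white spectrum", {
  fs <- 250
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  s <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(s$freqs[which.max(s$power)], 10)
  expect_equal(median(diff(s$freqs)), 0.1, tolerance = 1e-9)
  # floor((300 - 10)/5) + 1 = 59 epochs
  expect_equal(s$n_epochs, 59L)

  w <- withr::with_seed(4, rnorm(fs * 300))
  sw <- welch_psd(w, fs)
  sel <- sw$freqs >= 1 & sw$freqs <= 65
  slope <- unname(coef(lm(log10(sw$power[sel]) ~
                            log10(sw$freqs[sel])))[2])
  expect_lt(abs(slope), 0.1)

  expect_error(welch_psd(rnorm(100), fs), "at least")
  # amplitude mode halves the apparent exponent scale
  p <- timeseries_params(offset = 0, knee = 0, exponent = 2,
                         alpha_amplitude = 0)
  x <- simulate_parcel_timeseries(p, fs = fs, duration = 200, seed = 9)
  sa <- welch_psd(x, fs, magnitude = "amplitude")
  sel <- sa$freqs >= 1 & sa$freqs <= 65
  slope_a <- unname(coef(lm(log10(sa$power[sel]) ~
                              log10(sa$freqs[sel])))[2])
  expect_equal(slope_a, -1, tolerance = 0.15)
})

test_that("interpolate_line_noise touches only the band interior", {
  f <- seq(40, 60, by = 0.1)
  # linear spectrum: idempotent within 1e-12
  lin <- power_spectrum(f, 2 + 0.1 * f)
  out <- interpolate_line_noise(lin, line_freqs = 50)
  expect_equal(out$power, lin$power, tolerance = 1e-12)

  # unit spectrum with a spike at 50 Hz: restored to 1
  sp <- rep(1, length(f)); sp[f == 50] <- 10
  out2 <- interpolate_line_noise(power_spectrum(f, sp), line_freqs = 50)
  expect_equal(out2$power[f == 50], 1)

  # bins outside the band are bit-identical
  ar <- power_spectrum(f, withr::with_seed(2, runif(length(f), 1, 3)))
  out3 <- interpolate_line_noise(ar, line_freqs = 50)
  outside <- abs(f - 50) > 2
  expect_identical(out3$power[outside], ar$power[outside])
  # idempotence on arbitrary input
  expect_equal(interpolate_line_noise(out3, line_freqs = 50)$power,
               out3$power)

  # band exceeding support errors; fully-above-support bands skipped
  expect_error(interpolate_line_noise(power_spectrum(f, sp),
                                      line_freqs = 59.5),
               "support")
  expect_identical(
    interpolate_line_noise(power_spectrum(f, sp),
                           line_freqs = 150)$power, sp)
})

test_that("fit_spectral_model recovers exact power laws and knees", {
  # P = 1/f^2 (k = 0): chi = 2 +/- 0.05, no peaks, fixed mode
  fit <- fit_spectral_model(model_spectrum(b = 0, k = 0, chi = 2,
                                           peaks = NULL))
  expect_equal(fit$aperiodic$exponent, 2, tolerance = 0.05)
  expect_equal(nrow(fit$peaks), 0L)
  expect_identical(fit$aperiodic$mode, "fixed")
  expect_true(is.na(fit$aperiodic$knee_frequency))

  # b=1, k=100, chi=2 + 10 Hz peak: chi +/- 0.1, center +/- 0.2 Hz
  fit2 <- fit_spectral_model(model_spectrum(b = 1, k = 100, chi = 2))
  expect_equal(fit2$aperiodic$exponent, 2, tolerance = 0.1)
  expect_identical(fit2$aperiodic$mode, "with_knee")
  expect_equal(fit2$aperiodic$knee_frequency, 10, tolerance = 0.5)
  expect_equal(nrow(fit2$peaks), 1L)
  expect_equal(fit2$peaks$center_frequency, 10, tolerance = 0.2)
  expect_gt(fit2$peaks$peak_power, 0)
  expect_between(fit2$peaks$bandwidth, 2, 16)

  expect_error(fit_spectral_model(power_spectrum(seq(0.1, 80, 0.1),
                                                 rep(0, 800))),
               "non-positive")
})

test_that("near-power-law spectra trigger the fixed-mode knee fallback", {
  fit <- fit_spectral_model(model_spectrum(b = 0.5, k = 0, chi = 1.5,
                                           peaks = NULL, noise_sd = 0.03))
  expect_identical(fit$aperiodic$mode, "fixed")
  expect_true(is.na(fit$aperiodic$knee_frequency))
  expect_equal(fit$aperiodic$exponent, 1.5, tolerance = 0.1)
})

test_that("extract_alpha applies the reference window and tie rules", {
  ref <- model_spectrum(b = 1, k = 50, chi = 2,
                        peaks = data.frame(cf = 10, h = 0.9, bw = 2))
  mk_peaks <- function(...) {
    d <- data.frame(...)
    names(d) <- c("center_frequency", "peak_power", "bandwidth")
    d
  }
  peaks <- list(
    # two in-window candidates: 0.5 beats 0.3
    mk_peaks(c(9, 11), c(0.3, 0.5), c(3, 3)),
    # 13.5 outside the [7, 13] window (10 +/- bw/2 +/- 2), 11.5 inside
    mk_peaks(c(13.5, 11.5), c(0.9, 0.2), c(3, 3)),
    # no candidate anywhere: missing
    mk_peaks(numeric(0), numeric(0), numeric(0)),
    # peak outside window only: missing
    mk_peaks(5.5, 0.8, 3))
  res <- extract_alpha(peaks, ref)
  expect_equal(attr(res, "window"), c(7, 13), tolerance = 0.2)
  expect_equal(res$alpha_frequency[1], 11)
  expect_equal(res$alpha_power[1], 0.5)
  expect_equal(res$alpha_frequency[2], 11.5)
  expect_true(all(is.na(res$alpha_frequency[3:4])))
  expect_true(all(is.na(res$alpha_power[3:4])))

  # reference without an alpha peak: fall back to highest in 7-13
  ref0 <- model_spectrum(b = 1, k = 50, chi = 2, peaks = NULL)
  res0 <- extract_alpha(peaks, ref0)
  expect_null(attr(res0, "window"))
  expect_equal(res0$alpha_frequency[2], 11.5)
  expect_error(extract_alpha(peaks, NULL), "reference")
})

test_that("summarize_spectrum: analytic AUC sum and knee conversion", {
  # constant aperiodic power c on the 641-bin grid: auc = 641 c
  cst <- list(offset = log10(3), knee = 0, exponent = 1e-9,
              mode = "fixed", knee_frequency = NA)
  # chi ~ 0: f^chi ~ 1, power = 3 everywhere
  expect_equal(summarize_spectrum(cst)$auc, 641 * 3, tolerance = 1e-6)

  withk <- list(offset = 1, knee = 100, exponent = 2, mode = "with_knee",
                knee_frequency = 100^(1 / 2))
  s <- summarize_spectrum(withk)
  expect_equal(s$knee_frequency, 10)
  f <- seq(1, 65, by = 0.1)
  expect_equal(s$auc, sum(10 / (100 + f^2)))

  fixed <- list(offset = 1, knee = 0, exponent = 2, mode = "fixed",
                knee_frequency = NA)
  expect_true(is.na(summarize_spectrum(fixed)$knee_frequency))
})
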