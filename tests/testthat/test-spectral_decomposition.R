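# IRASA decomposition, band parameterization, slope and HFA indices.

test_that("compute_psd behaves like a calibrated Welch estimator", {
  fs <- 256
  expect_true(all(compute_psd(numeric(fs * 4), fs)$power == 0))

  # unit 10 Hz sinusoid: dominant bin at 10 Hz, low leakage
  t <- (0:(fs * 8 - 1)) / fs
  ps <- compute_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(ps$freq[which.max(ps$power)], 10)
  off <- ps$power[abs(ps$freq - 10) > 2]
  expect_lt(max(off), 0.01 * max(ps$power))

  # Parseval on white noise: integrated density ~ variance
  set.seed(1)
  x <- rnorm(fs * 30)
  ps <- compute_psd(x, fs, fmax = fs / 2)
  expect_equal(sum(ps$power) * (ps$freq[2] - ps$freq[1]), var(x),
               tolerance = 0.05)

  expect_error(compute_psd(rnorm(10), fs),
               class = "ecog_invalid_argument")
})

test_that("irasa separates fractal from oscillatory content", {
  fs <- 512
  x <- make_spectral_signal(1, fs = fs, dur = 60, chi = 1.5)
  ir <- irasa(x, fs, fmax = 100)

  # additivity is exact before clamping
  expect_identical(ir$original - ir$fractal, ir$oscillatory)

  # pure 1/f: oscillatory residual under 5% of fractal power (5-45 Hz);
  # the residual is Welch estimation noise, so a long segment is used
  xl <- make_spectral_signal(1, fs = fs, dur = 240, chi = 1.5)
  irl <- irasa(xl, fs, fmax = 100)
  k <- irl$freq >= 5 & irl$freq <= 45
  expect_lt(median(abs(irl$oscillatory[k])) / median(irl$fractal[k]), 0.05)

  # injected 10 Hz rhythm: oscillatory peak lands on 10 Hz
  x10 <- x + sin(2 * pi * 10 * (0:(length(x) - 1)) / fs)
  ir10 <- irasa(x10, fs, fmax = 100)
  kk <- ir10$freq >= 2
  expect_equal(ir10$freq[kk][which.max(ir10$oscillatory[kk])], 10,
               tolerance = 0.5)

  expect_error(irasa(x, fs, factors = numeric(0)),
               class = "ecog_invalid_argument")
})

test_that("fractal slope is robust to an added oscillation", {
  fs <- 512
  sl <- vapply(1:3, function(s) {
    x <- make_spectral_signal(s, fs = fs, dur = 40, chi = 1.5)
    x8 <- x + Re(ecogwaves:::narrowband_carrier(length(x), fs, 8, 4)) *
      sqrt(2) * 0.5
    c(fit_fractal_slope(irasa(x, fs))$slope,
      fit_fractal_slope(irasa(x8, fs))$slope)
  }, c(0, 0))
  expect_lt(max(abs(sl[2, ] - sl[1, ])), 0.1)
})

test_that("clamp_negative zeroes only negative power", {
  v <- c(1, 2, 3)
  expect_identical(clamp_negative(v), v)
  expect_identical(clamp_negative(c(1, -3, 2)), c(1, 0, 2))

  # a strong injected oscillation is never clamped at its peak bins
  fs <- 512
  x <- make_spectral_signal(2, fs = fs, dur = 40, chi = 1.5,
                            bumps = list(list(f = 10, fwhm = 3, amp = 1)))
  ir <- irasa(x, fs)
  pk <- ir$freq >= 9 & ir$freq <= 11
  expect_true(all(ir$oscillatory[pk] > 0))
})

test_that("Gaussian band model recovers injected alpha and beta bumps", {
  res <- t(vapply(1:5, function(s) {
    x <- make_spectral_signal(s, dur = 60,
                              bumps = list(list(f = 8, fwhm = 4, amp = 0.5),
                                           list(f = 18, fwhm = 6, amp = 0.35)))
    b <- fit_rhythm_bands(clamp_negative(irasa(x, 512, fmax = 130)))$bands
    c(b$center[b$label == "alpha"], b$fwhm[b$label == "alpha"],
      b$center[b$label == "beta"], b$fwhm[b$label == "beta"])
  }, numeric(4)))
  expect_lt(abs(mean(res[, 1]) - 8), 0.25)
  expect_lt(abs(mean(res[, 3]) - 18), 0.25)
  expect_lt(abs(mean(res[, 2]) - 4) / 4, 0.2)
  expect_lt(abs(mean(res[, 4]) - 6) / 6, 0.2)
})

test_that("auto model order adds a third term only for sub-5 Hz peaks", {
  x2 <- make_spectral_signal(3, dur = 60,
                             bumps = list(list(f = 8, fwhm = 4, amp = 0.5),
                                          list(f = 18, fwhm = 6, amp = 0.35)))
  f2 <- fit_rhythm_bands(clamp_negative(irasa(x2, 512, fmax = 130)))
  expect_equal(f2$model_order, 2)

  x3 <- make_spectral_signal(3, dur = 60,
                             bumps = list(list(f = 3, fwhm = 2, amp = 0.8),
                                          list(f = 8, fwhm = 4, amp = 0.5),
                                          list(f = 18, fwhm = 6, amp = 0.35)))
  f3 <- fit_rhythm_bands(clamp_negative(irasa(x3, 512, fmax = 130)))
  expect_equal(f3$model_order, 3)
  expect_setequal(f3$bands$label, c("low", "alpha", "beta"))
  # alpha/beta centers barely move when the low bump is added
  expect_lt(abs(f3$bands$center[f3$bands$label == "alpha"] -
                  f2$bands$center[f2$bands$label == "alpha"]), 0.5)
  expect_lt(abs(f3$bands$center[f3$bands$label == "beta"] -
                  f2$bands$center[f2$bands$label == "beta"]), 0.5)

  expect_error(fit_rhythm_bands(list(freq = 1:45, power = numeric(45))),
               class = "ecog_no_rhythm")
})

test_that("fit_fractal_slope is exact on noiseless power laws", {
  freq <- 1:128
  for (chi in c(0, 0.5, 2, 3)) {
    f <- fit_fractal_slope(list(freq = freq, power = freq^(-chi)))
    expect_equal(f$slope, -chi, tolerance = 1e-10)
    expect_gte(f$r_squared, if (chi == 0) 0 else 1 - 1e-10)
  }
  # multiplying by f^(-0.5) lowers the slope by exactly 0.5
  base <- freq^(-1.2)
  s1 <- fit_fractal_slope(list(freq = freq, power = base))$slope
  s2 <- fit_fractal_slope(list(freq = freq, power = base * freq^(-0.5)))$slope
  expect_equal(s2 - s1, -0.5, tolerance = 0.02)
  bad <- base; bad[40] <- -1   # non-positive power inside the fit band
  expect_error(fit_fractal_slope(list(freq = freq, power = bad)),
               class = "ecog_invalid_argument")
})

test_that("hfa_power averages fractal power over 60-120 Hz", {
  freq <- 0:130
  expect_equal(hfa_power(list(freq = freq, power = rep(1, 131))), 1)
  # doubling broadband amplitude quadruples power
  x <- make_spectral_signal(4, dur = 20, chi = 0.5)
  p1 <- hfa_power(compute_psd(x, 512, fmax = 130))
  p2 <- hfa_power(compute_psd(2 * x, 512, fmax = 130))
  expect_equal(p2 / p1, 4, tolerance = 1e-9)
  expect_error(hfa_power(list(freq = 0:50, power = rep(1, 51))),
               class = "ecog_invalid_argument")
})

test_that("slope fits on synthetic fractal spectra are clean (r2 >= 0.95)", {
  r2 <- vapply(1:5, function(s) {
    x <- make_spectral_signal(s + 10, dur = 40, chi = 1.5)
    fit_fractal_slope(irasa(x, 512))$r_squared
  }, 0)
  expect_gte(mean(r2), 0.95)
})
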