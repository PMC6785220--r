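# Generator module: fractal background, traveling oscillations, dataset
# assembly, grasp-choice forward model.

test_that("fractal background matches the requested exponent", {
  fs <- 512
  # white noise: 30-50 Hz log-log slope ~ 0 (mean of 3 long realizations)
  ps1 <- compute_psd(generate_fractal_background(1, fs * 120, fs, 0,
                                                 seed = 1)[, 1], fs)
  k <- ps1$freq >= 30 & ps1$freq <= 50
  sl0 <- vapply(1:3, function(s) {
    x <- generate_fractal_background(1, fs * 120, fs, 0, seed = s)[, 1]
    ps <- compute_psd(x, fs)
    unname(coef(lm(log10(ps$power[k]) ~ log10(ps$freq[k])))[2])
  }, 0)
  expect_lt(abs(mean(sl0)), 0.1)

  # chi = 1.5, 512 Hz, 60 s: Welch slope -1.5 +/- 0.15 (mean of 5 seeds)
  sl <- vapply(1:5, function(s) {
    x <- generate_fractal_background(1, fs * 60, fs, 1.5, seed = s)[, 1]
    ps <- compute_psd(x, fs)
    unname(coef(lm(log10(ps$power[k]) ~ log10(ps$freq[k])))[2])
  }, 0)
  expect_lt(abs(mean(sl) + 1.5), 0.15)
})

test_that("fractal background is deterministic and validates input", {
  a <- generate_fractal_background(2, 1024, 256, 1, seed = 42)
  b <- generate_fractal_background(2, 1024, 256, 1, seed = 42)
  expect_identical(a, b)
  # channels independent: near-zero correlation (white noise, so samples
  # are uncorrelated in time and the correlation estimate is tight)
  w <- generate_fractal_background(2, 8192, 256, 0, seed = 7)
  expect_lt(abs(cor(w[, 1], w[, 2])), 0.05)
  expect_error(generate_fractal_background(1, 0, 256, 1),
               class = "ecog_invalid_argument")
  expect_error(generate_fractal_background(1, 100, 256, -1),
               class = "ecog_invalid_argument")
})

test_that("traveling oscillation imposes the analytic phase-lag plane", {
  geom <- grid_geometry()
  # f = 10 Hz, v = 20 cm/s, electrodes 1 cm apart along u: lag = pi
  spec <- oscillation_spec(10, 3, direction = 0, speed = 20)
  osc <- generate_traveling_oscillation(geom, spec, 512, 256, seed = 1)
  p_cm <- geom$x / 10
  lag_per_cm <- 2 * pi * 10 / 20   # = pi
  expected <- ecogwaves:::wrap_pi(-lag_per_cm * p_cm)
  expect_lt(max(abs(ecogwaves:::wrap_pi(osc$phase_offsets - expected))),
            1e-9)
  d <- abs(ecogwaves:::wrap_pi(osc$phase_offsets[2] - osc$phase_offsets[1]))
  expect_equal(d, pi, tolerance = 1e-9)  # electrodes 1,2 are 10 mm apart in x

  # synchronous mode: all pairwise circular phase differences are zero
  sync <- generate_traveling_oscillation(
    geom, oscillation_spec(10, 3, speed = Inf), 512, 256, seed = 1)
  expect_true(all(sync$phase_offsets == 0))

  # direction theta vs theta + 180: phase-offset maps negated
  s1 <- generate_traveling_oscillation(
    geom, oscillation_spec(10, 3, direction = 40, speed = 20), 256, 256,
    seed = 2)
  s2 <- generate_traveling_oscillation(
    geom, oscillation_spec(10, 3, direction = 220, speed = 20), 256, 256,
    seed = 2)
  expect_equal(ecogwaves:::wrap_pi(s1$phase_offsets + s2$phase_offsets),
               rep(0, nrow(geom)), tolerance = 1e-9)

  expect_error(oscillation_spec(10, 3, speed = 0),
               class = "ecog_invalid_argument")
})

test_that("imposed phase-lag field is an exact plane before noise", {
  geom <- grid_geometry()
  spec <- oscillation_spec(8, 4, direction = 72, speed = 25)
  osc <- generate_traveling_oscillation(geom, spec, 256, 256, seed = 3)
  # planar fit of the *unwrapped* analytic offsets
  u <- c(cos(72 * pi / 180), sin(72 * pi / 180))
  raw <- -2 * pi * 8 / 25 * ((cbind(geom$x, geom$y) / 10) %*% u)
  fit <- lm(raw ~ geom$x + geom$y)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_lt(max(abs(ecogwaves:::wrap_pi(raw) - osc$phase_offsets)), 1e-9)
})

test_that("assemble_dataset writes a consistent, round-trippable bundle", {
  dir <- file.path(tempdir(), "ds")
  geom <- grid_geometry(4, 4, 10)
  tsp <- trial_spec(6, 2, trial_duration = 2, baseline_duration = 1)
  gt <- ground_truth(seed = 7)
  rec <- assemble_dataset(geom, tsp, gt, dir = dir, sample_rate = 256)
  # 6 trials/session x 2 sessions -> 12 event rows
  expect_equal(nrow(rec$events), 12)
  expect_true(all(c("onset", "duration", "hand", "orientation", "session",
                    "response") %in% names(rec$events)))
  # hand alternates in blocks of 10 (here: first 6 all left)
  expect_true(all(rec$events$hand[1:6] == "left"))

  # ground truth round trip
  gt2 <- read_ground_truth(file.path(dir, "ground_truth.json"))
  expect_equal(gt2$fractal_exponent, gt$fractal_exponent)
  expect_equal(gt2$oscillations$alpha$center_freq,
               gt$oscillations$alpha$center_freq)
  expect_equal(gt2$oscillations$beta$amplitude_by_condition,
               gt$oscillations$beta$amplitude_by_condition)
  expect_equal(gt2$behavior$left, gt$behavior$left)
  expect_equal(gt2$seed, gt$seed)

  # EDF round trip within 16-bit quantization
  back <- read_recording(file.path(dir, sprintf("session-%02d.edf", 1:2)),
                         file.path(dir, "electrodes.tsv"),
                         file.path(dir, "events.tsv"),
                         file.path(dir, "ground_truth.json"))
  q <- diff(range(rec$signals[[1]])) / 65535
  expect_lt(max(abs(back$signals[[1]] - rec$signals[[1]])), 2 * q)
  expect_equal(back$sample_rate, 256)
  expect_error(assemble_dataset(geom, trial_spec(6, 1, trial_duration = -1)),
               class = "ecog_invalid_argument")
})

test_that("grasp responses follow the sine law", {
  or <- seq(0, 336, by = 24)
  # a = 0: Bernoulli(c), empirical rate -> c
  tab <- generate_grasp_responses(or, c(a = 0, phi0 = 0, c = 0.3),
                                  n_per_orientation = 200, seed = 1)
  expect_lt(abs(mean(tab$overhand) - 0.3), 0.03)

  # noiseless mode: deterministic, two 50% crossings per cycle
  det <- generate_grasp_responses(or, c(a = 0.4, phi0 = 0, c = 0.5),
                                  n_per_orientation = 1, noiseless = TRUE)
  p <- 0.4 * sin(or * pi / 180) + 0.5
  expect_equal(det$overhand, as.integer(p >= 0.5))
  flips <- sum(diff(c(det$overhand, det$overhand[1])) != 0)
  expect_equal(flips, 2)

  # determinism + input validation
  expect_identical(
    generate_grasp_responses(or, c(a = .2, phi0 = 10, c = .5), 5, seed = 3),
    generate_grasp_responses(or, c(a = .2, phi0 = 10, c = .5), 5, seed = 3))
  expect_error(generate_grasp_responses(or, c(a = 0, phi0 = 0, c = .5), 0),
               class = "ecog_invalid_argument")
})
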