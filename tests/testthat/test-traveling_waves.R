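# Filtering, phase extraction, planar projection, gradients, PGD,
# direction/speed, nulls, circular statistics.

test_that("bandpass has unit passband gain and strong stopband rejection", {
  fs <- 256
  t <- (0:(fs * 4 - 1)) / fs
  at <- function(f, center, fwhm) {
    y <- bandpass(sin(2 * pi * f * t), fs, center, fwhm)
    sqrt(mean(y[fs:(3 * fs)]^2)) / sqrt(0.5)
  }
  expect_equal(at(10, 10, 4), 1, tolerance = 0.05)
  expect_lt(at(20, 10, 4), 0.1)            # 2x center: > 20 dB down
  expect_lt(sqrt(mean(bandpass(rep(1, fs * 2), fs, 10, 4)^2)), 0.05)  # DC

  # zero phase: peak cross-correlation with the input at lag 0
  x <- sin(2 * pi * 10 * t)
  y <- bandpass(x, fs, 10, 4)
  cc <- ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(bandpass(x, fs, 200, 20), class = "ecog_invalid_argument")
})

test_that("instantaneous phase follows the analytic-signal conventions", {
  fs <- 256
  t <- (0:(fs * 4 - 1)) / fs
  pf <- instantaneous_phase(cos(2 * pi * 8 * t))
  inner <- (fs):(3 * fs)
  # unwrapped slope = 2 pi f
  dph <- diff(pf$phase[inner])
  slope <- mean(ecogwaves:::wrap_pi(dph)) * fs
  expect_equal(slope, 2 * pi * 8, tolerance = 0.01 * 2 * pi * 8)
  # phase 0 at signal peaks (cosine convention)
  pk <- which.max(cos(2 * pi * 8 * t[inner]))
  expect_lt(abs(pf$phase[inner][pk]), 0.05)
  # flat amplitude envelope away from edges
  amp <- pf$amplitude[inner]
  expect_lt((max(amp) - min(amp)) / mean(amp), 0.04)
  expect_wrapped(pf$phase)
})

test_that("project_to_plane preserves planar geometry deterministically", {
  geom <- grid_geometry()
  pr <- project_to_plane(geom)
  # orthonormal basis
  expect_equal(t(pr$basis) %*% pr$basis, diag(2), tolerance = 1e-12)
  # coplanar grid: pairwise distances preserved exactly
  d3 <- dist(cbind(geom$x, geom$y, geom$z))
  d2 <- dist(pr$coords)
  expect_equal(as.vector(d2), as.vector(d3), tolerance = 1e-9)

  # rigid rotation of inputs: distances still preserved
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- as.matrix(cbind(geom$x, geom$y, geom$z)) %*% R
  pr2 <- project_to_plane(rot)
  expect_equal(as.vector(dist(pr2$coords)), as.vector(d3),
               tolerance = 1e-9)

  expect_error(project_to_plane(cbind(1:5, 2 * (1:5), 0 * (1:5))),
               class = "ecog_invalid_argument")
})

test_that("phase_gradient recovers planar fields and circular structure", {
  geom <- grid_geometry()
  pr <- project_to_plane(geom)
  co <- pr$coords / 10                       # cm
  phi <- ecogwaves:::wrap_pi(-0.5 * co[, 1]) # k = (0.5, 0) rad/cm
  g <- phase_gradient(phi, pr)
  expect_equal(unname(g$gx[1, !is.na(g$gx[1, ])]),
               rep(-0.5, sum(!is.na(g$gx[1, ]))), tolerance = 0.025)
  expect_lt(max(abs(g$gy), na.rm = TRUE), 1e-9)

  # uniform phase: zero gradient
  g0 <- phase_gradient(rep(1, nrow(geom)), pr)
  expect_lt(max(abs(c(g0$gx, g0$gy)), na.rm = TRUE), 1e-12)

  # adding 2 pi leaves gradients unchanged
  g2 <- phase_gradient(phi + 2 * pi, pr)
  expect_equal(g$gx, g2$gx, tolerance = 1e-9)
})

test_that("pgd and direction/speed satisfy their defining identities", {
  geom <- grid_geometry()
  pr <- project_to_plane(geom)
  co <- pr$coords / 10
  phi <- ecogwaves:::wrap_pi(-0.5 * co[, 1])
  g <- phase_gradient(phi, pr)
  expect_equal(pgd(g), 1, tolerance = 1e-9)          # aligned gradients
  expect_equal(wave_direction(g) %% 360, 0, tolerance = 1e-6)
  expect_equal(wave_speed(10, g), 2 * pi * 10 / 0.5, tolerance = 1e-6)

  # doubling gradient magnitudes halves the speed
  g2 <- phase_gradient(ecogwaves:::wrap_pi(-1.0 * co[, 1]), pr)
  expect_equal(wave_speed(10, g2), wave_speed(10, g) / 2,
               tolerance = 1e-6)

  # two equal and opposite gradients: PGD 0
  gg <- g
  gg$gx <- matrix(c(1, -1), 1, 2); gg$gy <- matrix(0, 1, 2)
  expect_equal(pgd(gg), 0, tolerance = 1e-12)

  # rotating the array (in-plane, active rotation by 90 deg) rotates the
  # reported direction by the same angle
  th <- pi / 2
  M <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  g_rot <- phase_gradient(phi, pr$coords %*% M)
  expect_lt(circ_diff_deg(wave_direction(g_rot)[1], 90), 1)

  # uniform phase: undefined direction flagged NA
  expect_true(is.na(wave_direction(phase_gradient(rep(0, 64), pr))))
})

test_that("end-to-end wave recovery within tolerance at 0 dB", {
  hits <- vapply(1:5, function(s) {
    w <- make_wave_phases(s, f = 5, speed = 15, direction = 125)
    pr <- project_to_plane(w$geom)
    g <- phase_gradient(w$phase, pr)
    truth <- plane_azimuth(pr, c(cos(125 * pi / 180),
                                 sin(125 * pi / 180), 0))
    est <- (ecogwaves:::circ_mean(
      wave_direction(g) * pi / 180) * 180 / pi) %% 360
    circ_diff_deg(est, truth)
  }, 0)
  expect_lt(max(hits), 10)
})

test_that("pgd_null separates waves from shuffled data", {
  w <- make_wave_phases(11, dur = 3)
  sub <- w$phase[seq(1, nrow(w$phase), by = 2), ]
  pr <- project_to_plane(w$geom)
  for (scheme in c("time_shuffle", "electrode_shuffle")) {
    r <- pgd_null(sub, pr, scheme, n_perm = 100, seed = 1)
    expect_equal(r$p, 1 / 101)            # total separation
    expect_true(all(r$null >= 0 & r$null <= 1))
  }
  expect_error(pgd_null(sub, pr, "time_shuffle", n_perm = 10),
               class = "ecog_invalid_argument")
})

test_that("directional consistency measures cross-trial alignment", {
  # identical directions: DC = 1
  d <- array(45, c(6, 3, 4))
  expect_equal(as.vector(directional_consistency(d)), rep(1, 12))
  # global rotation leaves DC unchanged
  set.seed(12)
  d2 <- array(runif(6 * 3 * 4, 0, 360), c(6, 3, 4))
  expect_equal(directional_consistency(d2),
               directional_consistency(d2 + 77), tolerance = 1e-9)
  # DC increases as trial-to-trial jitter decreases (MC)
  dcs <- vapply(c(120, 40, 5), function(sd_deg) {
    dd <- array(rnorm(40 * 2 * 2, mean = 90, sd = sd_deg), c(40, 2, 2))
    mean(directional_consistency(dd))
  }, 0)
  expect_true(all(diff(dcs) > 0))
  expect_error(directional_consistency(array(1, c(1, 2, 2))),
               class = "ecog_invalid_argument")
})

test_that("rayleigh test calibrates and detects concentration", {
  r <- rayleigh_test(rep(1.3, 100))
  expect_lt(r$p, 1e-15)
  expect_equal(r$R, 1)
  # shift invariance
  set.seed(13)
  a <- runif(50, 0, 2 * pi)
  expect_equal(rayleigh_test(a)$p, rayleigh_test(a + 2)$p,
               tolerance = 1e-9)
  # calibration on uniform angles
  rej <- mean(replicate(400, rayleigh_test(runif(200, 0, 2 * pi))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.035)
  expect_error(rayleigh_test(1:3), class = "ecog_invalid_argument")
})

test_that("direction KL divergence is calibrated", {
  set.seed(14)
  a <- runif(500, 0, 360)
  r <- direction_kl(a, a, n_perm = 0)
  expect_equal(r$kl, 0)
  # non-negativity on arbitrary samples
  b <- (rnorm(500, 90, 40)) %% 360
  expect_gte(direction_kl(a, b, n_perm = 0)$kl, 0)
  # shuffle p detects a real difference
  r2 <- direction_kl(a, b, n_perm = 200, seed = 2)
  expect_lt(r2$p, 0.01)
  expect_equal(sum(r2$pA), 1, tolerance = 1e-9)
})

test_that("relative phase maps reproduce the forward model", {
  geom <- grid_geometry()
  pr <- project_to_plane(geom)
  co <- pr$coords / 10
  k <- c(0.4, 0.2)
  phi <- ecogwaves:::wrap_pi(-(co %*% k))
  ph <- matrix(rep(phi, each = 5), 5, nrow(geom)) +
    matrix(rep(runif(5, -pi, pi), nrow(geom)), 5)  # common time phase
  ph <- ecogwaves:::wrap_pi(ph)
  ref <- 28
  m <- relative_phase_map(ph, ref)
  expected <- ecogwaves:::wrap_pi(phi - phi[ref])
  expect_equal(m[ref], 0, tolerance = 1e-12)
  expect_lt(max(abs(ecogwaves:::wrap_pi(m - expected))), 0.1)
  # circular averaging across the +/- pi seam
  two <- matrix(c(pi - 0.1, -pi + 0.1, 0, 0), 2, 2)
  mm <- relative_phase_map(two, 2)
  expect_equal(abs(mm[1]), pi, tolerance = 0.11)
  expect_error(relative_phase_map(ph, 999),
               class = "ecog_invalid_argument")
})
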