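# Time-frequency maps, session correction, baseline normalization,
# duration equalization, cluster permutation.

test_that("compute_tfr tracks stationary and step signals", {
  fs <- 128
  t <- (0:(fs * 4 - 1)) / fs
  x <- matrix(sin(2 * pi * 10 * t), ncol = 1)
  tfr <- compute_tfr(x, fs, t0 = 0)
  expect_equal(unique(round(diff(tfr$times), 10)), 0.05)  # exact 50 ms grid
  p10 <- tfr$power[1, 1, tfr$freqs == 10, ]
  inner <- p10[tfr$times > 1 & tfr$times < 3]
  expect_lt(sd(inner) / mean(inner), 0.05)

  # amplitude step at t = 1 s: 50% power-rise point at 1.0 +/- 0.1 s
  xs <- matrix(sin(2 * pi * 10 * t) * ifelse(t < 1, 1, 2), ncol = 1)
  tfrs <- compute_tfr(xs, fs, t0 = 0)
  ps <- tfrs$power[1, 1, tfrs$freqs == 10, ]
  lo <- mean(ps[tfrs$times < 0.6]); hi <- mean(ps[tfrs$times > 1.6])
  half <- lo + (hi - lo) / 2
  t50 <- tfrs$times[min(which(ps >= half))]
  expect_lt(abs(t50 - 1), 0.1)

  expect_error(compute_tfr(matrix(rnorm(50), ncol = 1), fs),
               class = "ecog_invalid_argument")
})

test_that("correct_session_offsets equalizes session means", {
  fs <- 128
  set.seed(2)
  tr <- array(rnorm(8 * 2 * fs * 2, sd = 1), c(8, 2, fs * 2))
  tr[5:8, , ] <- tr[5:8, , ] * 2          # session B globally scaled
  tfr <- compute_tfr(tr, fs, t0 = 0)
  sess <- rep(1:2, each = 4)
  # single session: identity
  expect_identical(correct_session_offsets(tfr, rep(1, 8))$power, tfr$power)
  cor1 <- correct_session_offsets(tfr, sess)
  m <- tapply(apply(cor1$power, 1, mean), sess, mean)
  expect_lt(abs(m[1] - m[2]) / abs(m[1]), 0.01)

  # label-permutation equivariance
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  a <- correct_session_offsets(tfr, sess)$power[perm, , , ]
  tfr_p <- tfr; tfr_p$power <- tfr$power[perm, , , , drop = FALSE]
  b <- correct_session_offsets(tfr_p, sess[perm])$power
  expect_equal(a, b[, , , ], tolerance = 1e-12)
})

test_that("baseline_normalize yields calibrated percent change", {
  fs <- 128
  # constant-amplitude signal: percent change ~ 0 everywhere
  t <- (0:(fs * 3 - 1)) / fs
  tr <- array(0, c(6, 1, length(t)))
  set.seed(3)
  for (i in 1:6) tr[i, 1, ] <- sin(2 * pi * 10 * t + runif(1) * 2 * pi)
  tfr <- compute_tfr(tr, fs, t0 = -1)
  bn <- baseline_normalize(tfr, n_boot = 200, seed = 1)
  expect_lt(max(abs(bn$power[, , tfr$freqs == 10, ])), 5)

  # doubled amplitude in the task window: +300% power at 10 Hz
  tr2 <- tr
  for (i in 1:6) tr2[i, 1, t > 1] <- 2 * tr2[i, 1, t > 1]
  tfr2 <- compute_tfr(tr2, fs, t0 = -1)
  bn2 <- baseline_normalize(tfr2, n_boot = 200, seed = 1)
  late <- bn2$power[, , tfr2$freqs == 10, bn2$times > 0.8]
  expect_equal(mean(late), 300, tolerance = 15)

  # bootstrap baseline converges to the plain across-trial mean
  bl <- apply(tfr$power[, , , bn$times >= -0.75 & bn$times <= -0.5,
                        drop = FALSE], c(2, 3), mean)
  expect_equal(as.vector(bn$baseline), as.vector(bl), tolerance = 0.01)

  expect_error(baseline_normalize(tfr, window = c(-9, -8)),
               class = "ecog_invalid_argument")
})

test_that("resample_to_common_duration is anti-aliased and endpoint-safe", {
  # already at target: unchanged
  x <- rnorm(40)
  expect_identical(resample_to_common_duration(x, 2, 2), x)

  # 4 s linear ramp -> 2 s ramp with preserved endpoints
  r <- seq(0, 1, length.out = 200)
  r2 <- resample_to_common_duration(r, 4, 2)
  expect_length(r2, 100)
  expect_lt(abs(r2[1] - 0), 0.01)
  expect_lt(abs(r2[100] - 1), 0.01)
  expect_lt(max(abs(r2 - seq(0, 1, length.out = 100))), 0.01)

  # content above the new Nyquist attenuated by > 20 dB
  fs <- 40
  t <- (0:159) / fs
  hf <- sin(2 * pi * 16 * t)            # 16 Hz > new Nyquist (10 Hz)
  out <- resample_to_common_duration(hf, 4, 2)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(hf^2)), 0.1)
})

test_that("cluster permutation finds real clusters and not fake ones", {
  set.seed(4)
  A <- matrix(rnorm(12 * 56), 12, 56)
  # condA == condB: no clusters at all
  r0 <- cluster_permutation_test(A, A, n_perm = 200)
  expect_null(r0$clusters)

  # injected contiguous effect, d ~ 1.5 on the paired difference
  B <- matrix(rnorm(12 * 56), 12, 56)
  eff <- 21:30
  A2 <- A; A2[, eff] <- A2[, eff] + 1.5 * sqrt(2)
  r1 <- cluster_permutation_test(A2, B, n_perm = 1000, seed = 9)
  sig <- significant_clusters(r1)
  expect_gte(nrow(sig), 1)
  covered <- unique(unlist(mapply(seq, sig$start, sig$end,
                                  SIMPLIFY = FALSE)))
  hit <- length(intersect(covered, eff)) / length(eff)
  expect_gte(hit, 0.8)
  expect_true(all(sig$sign == 1))

  expect_error(cluster_permutation_test(A[1, , drop = FALSE],
                                        B[1, , drop = FALSE]),
               class = "ecog_invalid_argument")
})

test_that("percent change is invariant to global channel rescaling", {
  set.seed(5)
  f <- array(abs(rnorm(6 * 2 * 30)) + 1, c(6, 2, 30))
  tm <- seq(-0.9, by = 0.05, length.out = 30)
  p1 <- percent_change(f, tm, n_boot = 100, seed = 1)
  p2 <- percent_change(f * 7, tm, n_boot = 100, seed = 1)
  expect_equal(p1, p2, tolerance = 1e-9)
})
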