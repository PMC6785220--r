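# Shared fixtures, built in code at test time.

# one-channel 1/f background plus optional narrowband bumps, for
# spectral-decomposition tests
make_spectral_signal <- function(seed, fs = 512, dur = 60, chi = 1.5,
                                 bumps = list()) {
  set.seed(seed)
  n <- fs * dur
  x <- generate_fractal_background(1, n, fs, chi)[, 1]
  for (b in bumps)
    x <- x + Re(ecogwaves:::narrowband_carrier(n, fs, b$f, b$fwhm)) *
      sqrt(2) * b$amp
  x
}

# forward-model traveling wave across the default grid, with white noise
# at the requested SNR (in signal-SD units; 1 = 0 dB)
make_wave_phases <- function(seed, f = 5, speed = 15, direction = 30,
                             fs = 256, dur = 4, noise_sd = 1,
                             geom = grid_geometry()) {
  set.seed(seed)
  n <- fs * dur
  spec <- oscillation_spec(f, 2, direction = direction, speed = speed,
                           amplitude = 1)
  osc <- generate_traveling_oscillation(geom, spec, n, fs)
  sig <- osc$signals
  if (noise_sd > 0)
    sig <- sig + matrix(rnorm(n * ncol(sig), 0, noise_sd), n, ncol(sig))
  filt <- bandpass(sig, fs, f, 3)
  ph <- instantaneous_phase(filt)$phase
  # drop filter edges and decimate for speed
  list(phase = ph[seq(round(0.25 * fs), n - round(0.25 * fs), by = 4), ,
                  drop = FALSE],
       geom = geom)
}

# tiny assembled dataset for pipeline tests
make_tiny_recording <- function(seed = 1, n_trials = 8, fs = 256,
                                dir = NULL) {
  geom <- grid_geometry(4, 4, 10)
  tsp <- trial_spec(n_trials, 1, trial_duration = 2, baseline_duration = 1)
  assemble_dataset(geom, tsp, ground_truth(seed = seed), dir = dir,
                   sample_rate = fs)
}

expect_wrapped <- function(x) {
  expect_true(all(x > -pi - 1e-12 & x <= pi + 1e-12))
}

# smallest circular difference in degrees
circ_diff_deg <- function(a, b) abs((a - b + 180) %% 360 - 180)
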