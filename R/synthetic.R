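# Synthetic ECoG generator: the forward model against which every
# downstream analysis is validated.  Signals are built from three
# ingredients -- a 1/f^chi arrhythmic background, narrowband traveling
# oscillations with exact planar phase lags, and broadband 60-120 Hz
# bursts -- combined per trial with condition-dependent gains.

#' Electrode grid geometry
#'
#' Builds a planar clinical-style electrode array.  The default is an
#' 8x8 grid with 10 mm inter-electrode spacing; strips are supported as
#' `1 x n`.  Electrodes are assigned an anatomical region (precentral /
#' postcentral / other, split along the grid midline by default, a stand-in
#' for the central sulcus) and an electrical-stimulation response type.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param spacing_mm nominal inter-electrode distance, mm.
#' @param stim_rows rows (1-based, counted along x) marked
#'   stimulation-positive; defaults to the central half of the array.
#' @return object of class `grid_geometry`: data.frame with columns
#'   `name, x, y, z` (mm), `region`, `stim_response`, plus attributes
#'   `spacing` and `dims`.
#' @export
grid_geometry <- function(n_rows = 8, n_cols = 8, spacing_mm = 10,
                          stim_rows = NULL) {
  if (spacing_mm <= 0) stop_invalid("spacing_mm must be > 0")
  if (n_rows < 1 || n_cols < 1) stop_invalid("grid dimensions must be >= 1")
  ix <- rep(seq_len(n_rows), times = n_cols)
  iy <- rep(seq_len(n_cols), each = n_rows)
  tab <- data.frame(
    name = sprintf("G%02d", seq_len(n_rows * n_cols)),
    x = (ix - 1) * spacing_mm,
    y = (iy - 1) * spacing_mm,
    z = 0,
    stringsAsFactors = FALSE)
  # central-sulcus stand-in: plane x = midline; precentral below, post above
  mid <- (n_rows - 1) * spacing_mm / 2
  tab$region <- ifelse(tab$x < mid, "precentral",
                       ifelse(tab$x > mid, "postcentral", "other"))
  stim_rows <- stim_rows %||%
    seq.int(max(1L, floor(n_rows / 4) + 1L), min(n_rows, ceiling(3 * n_rows / 4)))
  stim <- ix %in% stim_rows
  tab$stim_response <- "none"
  tab$stim_response[stim & tab$region == "precentral"] <- "motor"
  tab$stim_response[stim & tab$region == "postcentral"] <- "somatosensory"
  tab$stim_response[stim & tab$region == "other"] <- "both"
  structure(tab, class = c("grid_geometry", "data.frame"),
            spacing = spacing_mm, dims = c(n_rows, n_cols))
}

#' Oscillation specification for the forward model
#'
#' @param center_freq rhythm frequency f, Hz.
#' @param fwhm full width at half maximum of the spectral bump, Hz
#'   (power spectrum of the narrowband-noise carrier).
#' @param direction propagation azimuth in the array plane, degrees
#'   (0 = +x, counterclockwise).
#' @param speed propagation speed, cm/s; `Inf` = synchronous (no lag).
#' @param amplitude RMS amplitude in background-SD units.
#' @param amplitude_by_condition named numeric, relative task-window gain
#'   per condition (e.g. `c(contra = 0.8, ipsi = 1.0)`).
#' @param source_center,source_fwhm_mm optional spatial amplitude profile:
#'   Gaussian gain centered at `source_center` (xy, mm); `NULL` = uniform.
#' @param local_envelope_sd SD of a slow (<= 1 Hz) log-normal amplitude
#'   fluctuation applied independently per channel: rhythms wax and wane
#'   locally.  Pure amplitude modulation -- the traveling phase
#'   structure is untouched.  0 disables.
#' @export
oscillation_spec <- function(center_freq, fwhm, direction = 0, speed = Inf,
                             amplitude = 1,
                             amplitude_by_condition = c(contra = 1, ipsi = 1),
                             source_center = NULL, source_fwhm_mm = NULL,
                             local_envelope_sd = 0.5) {
  if (center_freq <= 0) stop_invalid("center_freq must be > 0")
  if (fwhm <= 0) stop_invalid("fwhm must be > 0")
  if (!is.infinite(speed) && speed <= 0)
    stop_invalid("speed must be > 0 (use Inf for synchronous)")
  structure(list(center_freq = center_freq, fwhm = fwhm,
                 direction = direction, speed = speed, amplitude = amplitude,
                 amplitude_by_condition = amplitude_by_condition,
                 source_center = source_center,
                 source_fwhm_mm = source_fwhm_mm,
                 local_envelope_sd = local_envelope_sd),
            class = "oscillation_spec")
}

#' Trial structure specification
#'
#' Defaults mirror the movement-imagery protocol: 60 trials per 10-minute
#' session, hand alternating in blocks of 10, cylinder orientation drawn
#' from 15 values 24 degrees apart.
#' @param n_trials_per_session,n_sessions counts.
#' @param trial_duration imagery epoch length, s (cylinder on screen).
#' @param baseline_duration pre-cylinder interval kept per epoch, s.
#' @export
trial_spec <- function(n_trials_per_session = 60, n_sessions = 2,
                       trial_duration = 3, baseline_duration = 1) {
  if (n_trials_per_session < 1 || n_sessions < 1)
    stop_invalid("trial counts must be >= 1")
  structure(list(n_trials_per_session = n_trials_per_session,
                 n_sessions = n_sessions,
                 trial_duration = trial_duration,
                 baseline_duration = baseline_duration,
                 orientations = seq(0, 336, by = 24),
                 hand_block = 10),
            class = "trial_spec")
}

#' 1/f^chi arrhythmic background
#'
#' Spectral shaping of white noise: Fourier amplitudes are multiplied by
#' f^(-chi/2) with random phases, so the expected power spectrum is an
#' exact power law.  Channels are independent; each is scaled to unit
#' standard deviation.
#'
#' @param n_channels,n_samples dimensions of the output.
#' @param sample_rate Hz.
#' @param exponent chi >= 0 (0 = white noise).
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return samples x channels matrix.
#' @export
generate_fractal_background <- function(n_channels, n_samples, sample_rate,
                                        exponent, seed = NULL) {
  if (n_samples <= 0) stop_invalid("n_samples must be positive")
  if (exponent < 0) stop_invalid("exponent must be >= 0")
  if (sample_rate <= 0) stop_invalid("sample_rate must be > 0")
  with_seed(seed, {
    n <- n_samples
    freqs <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) * sample_rate / n
    shape <- c(0, abs(freqs[-1])^(-exponent / 2))
    out <- matrix(0, n, n_channels)
    for (j in seq_len(n_channels)) {
      w <- stats::rnorm(n)
      y <- Re(stats::fft(shape * stats::fft(w), inverse = TRUE)) / n
      out[, j] <- y / stats::sd(y)
    }
    out
  })
}

# Complex narrowband carrier: analytic signal with a Gaussian spectral
# envelope (power-spectrum FWHM as requested) centered on f0.
narrowband_carrier <- function(n, fs, f0, fwhm) {
  freqs <- (0:(n - 1)) * fs / n
  sigma_pow <- fwhm / (2 * sqrt(2 * log(2)))
  sigma_amp <- sigma_pow * sqrt(2)   # amplitude envelope is sqrt of power
  env <- exp(-(freqs - f0)^2 / (2 * sigma_amp^2))
  env[freqs > fs / 2] <- 0           # analytic: positive frequencies only
  z <- stats::fft(env * (stats::rnorm(n) + 1i * stats::rnorm(n)),
                  inverse = TRUE) / n
  z / stats::sd(Re(z)) / sqrt(2)     # Re(z) has unit variance * 1/sqrt2...
}

#' Traveling narrowband oscillation across an electrode array
#'
#' Forward model: a single complex narrowband carrier is shared by all
#' electrodes, and electrode i receives the phase offset
#' `-(2*pi*f/v) * (p_i . u)` where `p_i` is its in-plane position (cm)
#' and `u` the unit propagation vector -- an exact plane wave in phase.
#'
#' @param geometry a [grid_geometry()].
#' @param spec an [oscillation_spec()].
#' @param n_samples,sample_rate output length and rate.
#' @param seed optional seed for the noise carrier.
#' @param carrier optional precomputed complex carrier (length n_samples).
#' @return list: `signals` (samples x channels), `phase_offsets` (rad per
#'   channel), `spatial_gain` (per channel).
#' @export
generate_traveling_oscillation <- function(geometry, spec, n_samples,
                                           sample_rate, seed = NULL,
                                           carrier = NULL) {
  if (!inherits(spec, "oscillation_spec")) stop_invalid("spec must be an oscillation_spec")
  if (n_samples <= 0) stop_invalid("n_samples must be positive")
  with_seed(seed, {
    if (is.null(carrier))
      carrier <- narrowband_carrier(n_samples, sample_rate,
                                    spec$center_freq, spec$fwhm)
    u <- c(cos(spec$direction * pi / 180), sin(spec$direction * pi / 180))
    p_cm <- cbind(geometry$x, geometry$y) / 10   # mm -> cm
    offs <- if (is.infinite(spec$speed)) rep(0, nrow(geometry)) else
      -2 * pi * spec$center_freq / spec$speed * as.vector(p_cm %*% u)
    gain <- rep(1, nrow(geometry))
    if (!is.null(spec$source_center)) {
      d2 <- (geometry$x - spec$source_center[1])^2 +
            (geometry$y - spec$source_center[2])^2
      s <- (spec$source_fwhm_mm %||% 20) / (2 * sqrt(2 * log(2)))
      gain <- exp(-d2 / (2 * s^2))
    }
    sig <- Re(outer(carrier, exp(1i * offs))) * spec$amplitude * sqrt(2)
    sig <- sweep(sig, 2, gain, `*`)
    les <- spec$local_envelope_sd %||% 0
    if (les > 0) {
      for (j in seq_len(ncol(sig))) {
        e <- fft_zero_phase_filter(stats::rnorm(nrow(sig)), sample_rate,
                                   function(f) as.numeric(f <= 1))
        sig[, j] <- sig[, j] * exp(les * (e / max(stats::sd(e), 1e-12)))
      }
      sig <- sig * exp(-les^2 / 2)    # keep the expected power scale
    }
    list(signals = sig, phase_offsets = wrap_pi(offs), spatial_gain = gain)
  })
}

#' Ground-truth record for a synthetic dataset
#'
#' Bundles every generator parameter so that downstream recovery tests
#' can compare estimates against known truth.  Serializes losslessly to
#' JSON via [write_ground_truth()] / [read_ground_truth()].
#'
#' @param fractal_exponent chi of the 1/f background.
#' @param oscillations named list of [oscillation_spec()]s
#'   (conventionally `alpha` and `beta`).
#' @param hfa_modulation relative task gain of 60-120 Hz broadband bursts
#'   in the contralateral condition (1 = none).
#' @param noise_level white sensor-noise SD in background-SD units.
#' @param envelope_jitter_sd SD of the log-normal per-trial amplitude
#'   jitter applied independently to each oscillation (0 = fixed).
#' @param broadband_gain_sd SD of a slow (<= 0.5 Hz) log-normal gain
#'   applied to the 1/f background, shared across channels within each
#'   trial: emulates global excitability drift, the shared broadband
#'   variance that inflates raw between-band envelope correlations.
#' @param demand_coupling 0-1: strength of a latent per-trial demand
#'   variable that delays both rhythms' task-envelope onset by up to
#'   `0.5 * demand_coupling` seconds, giving the two bands a shared
#'   trial-by-trial pattern structure (drives second-order similarity
#'   without inducing within-trial amplitude correlation at 0).
#' @param behavior per-hand sine-law parameters, a list like
#'   `list(left = c(a=.., phi0=.., c=..), right = ...)` with p(overhand) =
#'   a*sin(theta + phi0) + c.
#' @param seed master seed.
#' @export
ground_truth <- function(fractal_exponent = 1.5,
                         oscillations = list(
                           alpha = oscillation_spec(8, 4, direction = 90,
                                                    speed = 25, amplitude = 0.5,
                                                    amplitude_by_condition =
                                                      c(contra = 1.0, ipsi = 1.3)),
                           beta = oscillation_spec(18, 6, direction = 270,
                                                   speed = 60, amplitude = 0.35,
                                                   amplitude_by_condition =
                                                     c(contra = 0.8, ipsi = 1.0))),
                         hfa_modulation = 1.5,
                         noise_level = 0.1,
                         envelope_jitter_sd = 0,
                         broadband_gain_sd = 0.6,
                         demand_coupling = 0,
                         behavior = list(
                           left  = c(a = 0.4, phi0 = 45, c = 0.5),
                           right = c(a = 0.4, phi0 = -45, c = 0.5)),
                         seed = 1L) {
  structure(list(fractal_exponent = fractal_exponent,
                 oscillations = oscillations,
                 hfa_modulation = hfa_modulation,
                 noise_level = noise_level,
                 envelope_jitter_sd = envelope_jitter_sd,
                 broadband_gain_sd = broadband_gain_sd,
                 demand_coupling = demand_coupling,
                 behavior = behavior, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @param gt a `ground_truth` object.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(gt, path) {
  out <- unclass(gt)
  # jsonlite drops names of atomic vectors; convert to objects
  out$oscillations <- lapply(out$oscillations, function(o) {
    o <- unclass(o)
    o$amplitude_by_condition <- as.list(o$amplitude_by_condition)
    o
  })
  out$behavior <- lapply(out$behavior, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  oscs <- lapply(raw$oscillations, function(o)
    oscillation_spec(o$center_freq, o$fwhm, o$direction,
                     if (is.null(o$speed)) Inf else o$speed,  # Inf drops in JSON
                     o$amplitude, unlist(o$amplitude_by_condition),
                     o$source_center, o$source_fwhm_mm,
                     o$local_envelope_sd %||% 0))
  ground_truth(raw$fractal_exponent, oscs, raw$hfa_modulation,
               raw$noise_level, raw$envelope_jitter_sd, raw$broadband_gain_sd,
               raw$demand_coupling %||% 0,
               lapply(raw$behavior, unlist), raw$seed)
}

# Smooth task-window gain profile: ramps from 1 to `gain` over 250 ms at
# task onset and back after task offset.
task_gain_profile <- function(t, gain, t_on, t_off, ramp = 0.25) {
  w <- stats::plogis((t - t_on) / (ramp / 8)) *
       stats::plogis((t_off - t) / (ramp / 8))
  1 + (gain - 1) * w
}

#' Assemble a full synthetic recording with ground truth
#'
#' Builds per-session continuous signals trial by trial: 1/f background
#' (common per channel), traveling alpha/beta oscillations whose
#' task-window amplitude depends on the hand condition (defaults: +30%
#' ipsilateral alpha, -20% contralateral beta), and 60-120 Hz broadband
#' bursts co-modulated with the contralateral condition.  Writes an EDF
#' file per session plus BIDS-iEEG style electrodes/events tables and a
#' ground-truth JSON.
#'
#' @param geometry [grid_geometry()].
#' @param trials [trial_spec()].
#' @param gt [ground_truth()].
#' @param dir output directory (created if missing).
#' @param sample_rate Hz.
#' @param write if `FALSE`, return the in-memory recording only.
#' @return list of class `recording`: `signals` (list of per-session
#'   samples x channels matrices), `sample_rate`, `electrodes`, `events`,
#'   `ground_truth`, `paths`.
#' @export
assemble_dataset <- function(geometry, trials = trial_spec(),
                             gt = ground_truth(), dir = NULL,
                             sample_rate = 512, write = !is.null(dir)) {
  fs <- sample_rate
  bl <- trials$baseline_duration
  td <- trials$trial_duration
  gap <- 0.5
  if (bl <= 0 || td <= 0) stop_invalid("durations must be positive")
  epoch_len <- round((bl + td + gap) * fs)
  n_tr <- trials$n_trials_per_session
  n_ch <- nrow(geometry)

  set.seed(gt$seed)
  events <- NULL
  sessions <- vector("list", trials$n_sessions)
  hands <- rep(rep(c("left", "right"), each = trials$hand_block),
               length.out = n_tr)
  # grid is a left-hemisphere stand-in: right hand = contralateral
  cond_of <- function(hand) ifelse(hand == "right", "contra", "ipsi")
  t_ep <- (seq_len(epoch_len) - 1) / fs - bl   # time within epoch, s

  for (s in seq_len(trials$n_sessions)) {
    sess_gain <- exp(stats::rnorm(1, 0, 0.1))  # inter-session power offset
    orient <- sample(rep(trials$orientations,
                         length.out = n_tr))
    sig <- matrix(0, epoch_len * n_tr, n_ch)
    onsets <- numeric(n_tr)
    latent <- stats::runif(n_tr)
    for (k in seq_len(n_tr)) {
      idx <- ((k - 1) * epoch_len + 1):(k * epoch_len)
      cond <- cond_of(hands[k])
      shift <- 0.5 * gt$demand_coupling * latent[k]
      ep <- generate_fractal_background(n_ch, epoch_len, fs,
                                        gt$fractal_exponent)
      if (gt$broadband_gain_sd > 0) {
        # slow common gain on the arrhythmic background: excitability
        # drift shared by all channels (and hence by all bands)
        g <- fft_zero_phase_filter(stats::rnorm(epoch_len), fs,
                                   function(f) as.numeric(f <= 0.5))
        g <- g / max(stats::sd(g), 1e-12)
        ep <- ep * exp(gt$broadband_gain_sd * (g - mean(g)))
      }
      sig[idx, ] <- ep
      for (nm in names(gt$oscillations)) {
        spec <- gt$oscillations[[nm]]
        cgain <- spec$amplitude_by_condition[[cond]] %||% 1
        jit <- if (gt$envelope_jitter_sd > 0)
          exp(stats::rnorm(1, 0, gt$envelope_jitter_sd)) else 1
        osc <- generate_traveling_oscillation(geometry, spec, epoch_len, fs)
        prof <- task_gain_profile(t_ep, cgain, shift, td)
        sig[idx, ] <- sig[idx, ] + osc$signals * prof * jit
      }
      # broadband bursts co-modulated with the contra condition: shallow
      # 1/f^0.5 spectrum (population spiking raises broadband power and
      # flattens the slope, visible in the 60-120 Hz HFA readout)
      if (gt$hfa_modulation != 1 && cond == "contra") {
        hf <- generate_fractal_background(n_ch, epoch_len, fs, 0.5)
        prof <- task_gain_profile(t_ep, gt$hfa_modulation, 0, td) - 1
        sig[idx, ] <- sig[idx, ] + 0.5 * hf * prof
      }
      if (gt$noise_level > 0)
        sig[idx, ] <- sig[idx, ] +
          matrix(stats::rnorm(epoch_len * n_ch, 0, gt$noise_level),
                 epoch_len, n_ch)
      onsets[k] <- (k - 1) * epoch_len / fs + bl
    }
    sig <- sig * sess_gain * 50            # ~microvolt scale
    colnames(sig) <- geometry$name
    sessions[[s]] <- sig
    bp <- vapply(seq_len(n_tr), function(k) {
      pr <- gt$behavior[[hands[k]]]
      min(1, max(0, pr[["a"]] * sin((orient[k] + pr[["phi0"]]) * pi / 180) +
                   pr[["c"]]))
    }, 0)
    events <- rbind(events, data.frame(
      onset = onsets, duration = td, hand = hands,
      orientation = orient, session = s,
      response = ifelse(stats::rbinom(n_tr, 1, bp) == 1,
                        "overhand", "underhand"),
      latent_demand = latent,
      stringsAsFactors = FALSE))
  }

  rec <- structure(list(signals = sessions, sample_rate = fs,
                        electrodes = as.data.frame(geometry),
                        events = events, ground_truth = gt,
                        paths = NULL),
                   class = "recording")
  if (write) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      signals = file.path(dir, sprintf("session-%02d.edf",
                                       seq_len(trials$n_sessions))),
      electrodes = file.path(dir, "electrodes.tsv"),
      events = file.path(dir, "events.tsv"),
      ground_truth = file.path(dir, "ground_truth.json"))
    for (s in seq_len(trials$n_sessions))
      write_edf(sessions[[s]], fs, paths$signals[s], labels = geometry$name)
    utils::write.table(rec$electrodes, paths$electrodes, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(events, paths$events, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_ground_truth(gt, paths$ground_truth)
    rec$paths <- paths
  }
  rec
}

#' Simulated grasp choices under the sine law
#'
#' Bernoulli draws of the overhand choice with
#' p(overhand) = a*sin(theta + phi0) + c, clipped to `[0, 1]`.
#'
#' @param orientations cylinder orientations, degrees.
#' @param params named numeric `c(a=, phi0=, c=)` (phi0 in degrees).
#' @param n_per_orientation presentations per orientation.
#' @param seed optional seed.
#' @param noiseless if `TRUE`, choices are the rounded probabilities
#'   (deterministic psychometric pattern).
#' @return data.frame: orientation, trial, overhand (0/1).
#' @export
generate_grasp_responses <- function(orientations, params,
                                     n_per_orientation = 8, seed = NULL,
                                     noiseless = FALSE) {
  if (n_per_orientation <= 0) stop_invalid("n_per_orientation must be > 0")
  p <- params[["a"]] * sin((orientations + params[["phi0"]]) * pi / 180) +
       params[["c"]]
  p <- pmin(1, pmax(0, p))
  with_seed(seed, {
    tab <- expand.grid(trial = seq_len(n_per_orientation),
                       orientation = orientations)
    pp <- p[match(tab$orientation, orientations)]
    tab$overhand <- if (noiseless) as.integer(pp >= 0.5) else
      stats::rbinom(nrow(tab), 1, pp)
    tab[, c("orientation", "trial", "overhand")]
  })
}
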