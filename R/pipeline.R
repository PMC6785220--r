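# Orchestration: file I/O, epoching, configuration, and the end-to-end
# synthetic benchmark.

#' Read a recording from EDF + BIDS-iEEG style tables
#'
#' @param signal_paths character vector of EDF paths (one per session,
#'   in session order).
#' @param electrodes_path tab-separated table: name, x, y, z, region,
#'   stim_response.
#' @param events_path tab-separated table: onset, duration, hand,
#'   orientation, session (optionally response).
#' @param ground_truth_path optional ground-truth JSON.
#' @return object of class `recording`.
#' @export
read_recording <- function(signal_paths, electrodes_path, events_path,
                           ground_truth_path = NULL) {
  electrodes <- utils::read.delim(electrodes_path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z", "region", "stim_response")
  if (!all(need %in% names(electrodes)))
    ecog_error("ecog_schema_error",
               paste("electrodes table lacks columns:",
                     paste(setdiff(need, names(electrodes)), collapse = ", ")))
  events <- utils::read.delim(events_path, stringsAsFactors = FALSE)
  need_e <- c("onset", "duration", "hand", "orientation", "session")
  if (!all(need_e %in% names(events)))
    ecog_error("ecog_schema_error",
               paste("events table lacks columns:",
                     paste(setdiff(need_e, names(events)), collapse = ", ")))
  edfs <- lapply(signal_paths, read_edf)
  for (i in seq_along(edfs)) {
    bad <- setdiff(electrodes$name, edfs[[i]]$labels)
    if (length(bad))
      ecog_error("ecog_schema_error",
                 paste0("channels in electrodes table missing from EDF ", i,
                        ": ", paste(bad, collapse = ", ")))
  }
  fs <- edfs[[1]]$sample_rate
  signals <- lapply(edfs, function(e)
    e$signals[, electrodes$name, drop = FALSE])
  for (s in unique(events$session)) {
    ev <- events[events$session == s, ]
    dur <- nrow(signals[[s]]) / fs
    if (any(ev$onset + ev$duration > dur))
      ecog_error("ecog_validation_error",
                 sprintf("events in session %s extend beyond the recording", s))
  }
  gt <- if (!is.null(ground_truth_path) && file.exists(ground_truth_path))
    read_ground_truth(ground_truth_path) else NULL
  structure(list(signals = signals, sample_rate = fs,
                 electrodes = electrodes, events = events,
                 ground_truth = gt, paths = list(
                   signals = signal_paths, electrodes = electrodes_path,
                   events = events_path)),
            class = "recording")
}

#' Cut trial epochs out of a recording
#'
#' Onsets are snapped to the sample grid; epochs run from `from` to `to`
#' seconds around each event onset.
#'
#' @param rec a `recording`.
#' @param from,to epoch window relative to onset, s.
#' @param channels channel names (default: all).
#' @return list: `data` array `[trial, channel, sample]`, `times`
#'   (sample times, s), `events` (the trial table).
#' @export
epoch_recording <- function(rec, from = -1, to = 3, channels = NULL) {
  fs <- rec$sample_rate
  channels <- channels %||% rec$electrodes$name
  n_ep <- round((to - from) * fs)
  ev <- rec$events
  data <- array(0, c(nrow(ev), length(channels), n_ep))
  for (k in seq_len(nrow(ev))) {
    sig <- rec$signals[[ev$session[k]]]
    i0 <- round((ev$onset[k] + from) * fs) + 1
    if (i0 < 1 || i0 + n_ep - 1 > nrow(sig))
      ecog_error("ecog_validation_error",
                 sprintf("epoch for trial %d falls outside the recording", k))
    data[k, , ] <- t(sig[i0:(i0 + n_ep - 1), channels, drop = FALSE])
  }
  list(data = data, times = from + (seq_len(n_ep) - 1) / fs, events = ev)
}

#' Time-resolved 30-50 Hz spectral slope
#'
#' Per-trial, per-channel, per-time-point log-log linear slope of the
#' TFR over the reference band; the time-resolved companion of
#' [fit_fractal_slope()].
#'
#' @param tfr a [compute_tfr()] result (absolute power).
#' @param fit_band frequency range, Hz.
#' @return array `[trial, channel, time]`.
#' @export
slope_timecourse <- function(tfr, fit_band = c(30, 50)) {
  ridx <- which(tfr$freqs >= fit_band[1] & tfr$freqs <= fit_band[2] &
                  tfr$freqs > 0)
  if (length(ridx) < 3) stop_invalid("need >= 3 frequencies in fit band")
  lx <- log10(tfr$freqs[ridx])
  lxc <- lx - mean(lx)
  Y <- apply(tfr$power[, , ridx, , drop = FALSE], c(1, 2, 4), identity)
  Y <- log10(pmax(Y, .Machine$double.xmin))   # [freq, trial, ch, time]
  apply(Y * lxc, c(2, 3, 4), sum) / sum(lxc^2)
}

#' Percent change of a feature time course from its baseline
#'
#' @param feat array `[trial, channel, time]` (non-negative feature such
#'   as band power).
#' @param times time axis, s.
#' @param window baseline interval, s.
#' @param n_boot bootstrap resamples for the baseline mean.
#' @param seed optional RNG seed.
#' @param relative if `FALSE`, subtract the baseline instead of
#'   expressing percent change (for signed features like the slope).
#' @return array like `feat`.
#' @export
percent_change <- function(feat, times, window = c(-0.75, -0.50),
                           n_boot = 1000, seed = NULL, relative = TRUE) {
  bidx <- which(times >= window[1] & times <= window[2])
  if (!length(bidx)) stop_invalid("baseline window outside epoch")
  n_tr <- dim(feat)[1]
  bl_tr <- apply(feat[, , bidx, drop = FALSE], c(1, 2), mean)
  B <- with_seed(seed, {
    acc <- 0
    for (b in seq_len(n_boot))
      acc <- acc + colMeans(bl_tr[sample.int(n_tr, n_tr, TRUE), ,
                                  drop = FALSE])
    acc / n_boot
  })
  dm <- dim(feat)
  Bfull <- aperm(array(B, c(dm[2], dm[1], dm[3])), c(2, 1, 3))
  if (!relative) return(feat - Bfull)
  if (any(B <= 0)) stop_invalid("non-positive baseline for percent change")
  100 * (feat - Bfull) / Bfull
}

#' Pipeline configuration
#'
#' Single nested list of per-stage parameters with documented defaults;
#' any entry can be overridden via `...` (e.g.
#' `pipeline_config(seed = 7, waves = list(n_perm = 500))`).
#'
#' @param seed master seed; every stochastic stage derives its RNG
#'   stream from it.
#' @param out_dir output directory (`NULL` = in-memory only).
#' @param ... stage overrides, merged over the defaults.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    stages = c("simulate", "decompose", "select", "dynamics", "waves",
               "similarity", "behavior", "report"),
    simulate = list(n_rows = 8, n_cols = 8, spacing_mm = 10,
                    n_trials_per_session = 60, n_sessions = 2,
                    trial_duration = 3, baseline_duration = 1,
                    sample_rate = 512),
    decompose = list(max_pool_s = 120, fmax = 130,
                     factors = seq(1.1, 1.45, by = 0.05)),
    dynamics = list(epoch_from = -1, epoch_to = 3, fmax = 130,
                    baseline = c(-0.75, -0.50), n_boot = 1000,
                    n_perm = 2000, alpha = 0.05),
    waves = list(window = c(0, 2), decimate = 4, n_perm = 200,
                 n_bins = 36, max_trials = 40),
    behavior = list(half_range = 24))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(s)) %% 251 + 1)) %% .Machine$integer.max)
}

write_stage_table <- function(tab, path, cfg) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s seed=%d", config_hash(cfg), cfg$seed),
             con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
}

#' Run the full analysis pipeline on a synthetic or loaded recording
#'
#' Stage order: simulate -> decompose -> select -> dynamics -> waves ->
#' similarity -> behavior -> report.  Deterministic given `cfg$seed`.
#' Stages absent from `cfg$stages` are skipped (downstream stages that
#' need their products are skipped too, with a log entry).
#'
#' @param cfg a [pipeline_config()].
#' @param recording optional preloaded `recording` (skips `simulate`).
#' @return results bundle (list by stage), invisibly including `log`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), recording = NULL) {
  res <- list(config = cfg, log = character(0))
  say <- function(...) {
    msg <- sprintf(...)
    res$log <<- c(res$log, msg)
    message("[ecogwaves] ", msg)
  }
  on_stage <- function(s) s %in% cfg$stages
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  ## --- simulate -------------------------------------------------------
  if (is.null(recording)) {
    if (!on_stage("simulate"))
      stop_invalid("no recording given and simulate stage disabled")
    sim <- cfg$simulate
    geom <- grid_geometry(sim$n_rows, sim$n_cols, sim$spacing_mm)
    tsp <- trial_spec(sim$n_trials_per_session, sim$n_sessions,
                      sim$trial_duration, sim$baseline_duration)
    gt <- cfg$ground_truth %||% ground_truth(seed = cfg$seed)
    gt$seed <- cfg$seed
    say("simulate: %d electrodes, %d trials x %d sessions @ %g Hz",
        nrow(geom), sim$n_trials_per_session, sim$n_sessions,
        sim$sample_rate)
    recording <- assemble_dataset(geom, tsp, gt,
                                  dir = if (!is.null(out_dir))
                                    file.path(out_dir, "data"),
                                  sample_rate = sim$sample_rate)
  }
  rec <- recording
  res$recording <- rec
  fs <- rec$sample_rate
  ev <- rec$events
  hand_cond <- ifelse(ev$hand == "right", "contra", "ipsi")

  ## --- decompose ------------------------------------------------------
  if (on_stage("decompose")) {
    dc <- cfg$decompose
    stim <- select_stimulation_positive(rec$electrodes)
    ep <- epoch_recording(rec, 0, min(ev$duration), channels = stim$name)
    n_keep <- min(dim(ep$data)[1],
                  ceiling(dc$max_pool_s / min(ev$duration)))
    profiles <- vector("list", nrow(stim))
    names(profiles) <- stim$name
    osc_sum <- NULL
    for (j in seq_len(nrow(stim))) {
      pooled <- as.vector(t(ep$data[seq_len(n_keep), j, ]))
      sp <- clamp_negative(irasa(pooled, fs, dc$factors, fmax = dc$fmax))
      # the HFA readout band is clipped to the spectrum when the
      # sampling rate cannot support the full 60-120 Hz range
      hfa_band <- c(60, min(120, max(sp$freq)))
      profiles[[j]] <- list(spectrum = sp,
                            slope = fit_fractal_slope(sp),
                            hfa = if (hfa_band[1] < hfa_band[2])
                              hfa_power(sp, hfa_band) else NA_real_)
      osc_sum <- if (is.null(osc_sum)) sp$oscillatory else
        osc_sum + sp$oscillatory
    }
    mean_osc <- list(freq = profiles[[1]]$spectrum$freq,
                     power = osc_sum / nrow(stim))
    bands_fit <- fit_rhythm_bands(mean_osc)
    bands <- bands_fit$bands
    alpha_band <- with(bands[bands$label == "alpha", ],
                       c(center - fwhm / 2, center + fwhm / 2))
    beta_band <- with(bands[bands$label == "beta", ],
                      c(center - fwhm / 2, center + fwhm / 2))
    band_pow <- function(sp, band) {
      k <- sp$freq >= band[1] & sp$freq <= band[2]
      if (!any(k))   # degenerate narrow fit: use the nearest bin
        k <- which.min(abs(sp$freq - mean(band)))
      mean(sp$oscillatory[k])
    }
    feat <- data.frame(
      name = stim$name,
      alpha = vapply(profiles, function(p) band_pow(p$spectrum, alpha_band), 0),
      beta = vapply(profiles, function(p) band_pow(p$spectrum, beta_band), 0),
      hfa = vapply(profiles, function(p) p$hfa, NA_real_),
      slope = vapply(profiles, function(p) p$slope$slope, 0),
      slope_r2 = vapply(profiles, function(p) p$slope$r_squared, 0),
      stringsAsFactors = FALSE)
    res$decompose <- list(profiles = profiles, bands = bands,
                          alpha_band = alpha_band, beta_band = beta_band,
                          features = feat, stim = stim)
    say("decompose: alpha %.1f Hz, beta %.1f Hz; mean slope %.2f",
        bands$center[bands$label == "alpha"],
        bands$center[bands$label == "beta"], mean(feat$slope))
    if (!is.null(out_dir)) {
      write_stage_table(bands, file.path(out_dir, "bands.tsv"), cfg)
      write_stage_table(feat, file.path(out_dir, "spectral_features.tsv"), cfg)
    }
  }

  ## --- select ---------------------------------------------------------
  if (on_stage("select") && !is.null(res$decompose)) {
    feat <- res$decompose$features
    sel <- list(
      alpha = find_local_maxima(stats::setNames(feat$alpha, feat$name), "upper"),
      beta = find_local_maxima(stats::setNames(feat$beta, feat$name), "upper"),
      slope = find_local_maxima(stats::setNames(feat$slope, feat$name), "lower"))
    if (!anyNA(feat$hfa))
      sel$hfa <- find_local_maxima(stats::setNames(feat$hfa, feat$name),
                                   "upper")
    stim <- res$decompose$stim
    cat_tests <- lapply(sel, function(s) {
      reg <- stim$region[match(s$selected, stim$name)]
      counts <- c(pre = sum(reg == "precentral"),
                  post = sum(reg == "postcentral"))
      if (sum(counts) == 0) NULL else category_test(counts)
    })
    res$select <- list(selections = sel, category_tests = cat_tests)
    say("select: %d alpha, %d beta, %d hfa, %d slope local maxima",
        length(sel$alpha$selected), length(sel$beta$selected),
        length(sel$hfa$selected %||% character(0)),
        length(sel$slope$selected))
    if (!is.null(out_dir)) {
      tab <- do.call(rbind, lapply(names(sel), function(nm)
        data.frame(feature = nm, electrode = sel[[nm]]$selected,
                   threshold = sel[[nm]]$threshold, tail = sel[[nm]]$tail)))
      write_stage_table(tab, file.path(out_dir, "selections.tsv"), cfg)
    }
  }

  ## --- dynamics -------------------------------------------------------
  if (on_stage("dynamics") && !is.null(res$decompose)) {
    dy <- cfg$dynamics
    stim <- res$decompose$stim
    ep <- epoch_recording(rec, dy$epoch_from, dy$epoch_to,
                          channels = stim$name)
    tfr <- compute_tfr(ep$data, fs, t0 = dy$epoch_from, fmax = dy$fmax)
    tfr <- correct_session_offsets(tfr, ev$session)
    feats <- list(
      alpha = band_power(tfr, res$decompose$alpha_band,
                         fractal_correct = TRUE),
      beta = band_power(tfr, res$decompose$beta_band,
                        fractal_correct = TRUE),
      slope = slope_timecourse(tfr))
    if (max(tfr$freqs) > 60)
      feats$hfa <- band_power(tfr, c(60, min(120, max(tfr$freqs))))
    # percent change for power features, baseline shift for the slope;
    # oscillatory features can dip below zero after 1/f correction, so
    # normalize by the absolute-power baseline instead
    raw_alpha <- band_power(tfr, res$decompose$alpha_band)
    raw_beta <- band_power(tfr, res$decompose$beta_band)
    pc <- list(
      alpha = percent_change(raw_alpha, tfr$times, dy$baseline, dy$n_boot,
                             seed = cfg$seed + 11),
      beta = percent_change(raw_beta, tfr$times, dy$baseline, dy$n_boot,
                            seed = cfg$seed + 12),
      slope = percent_change(feats$slope, tfr$times, dy$baseline,
                             dy$n_boot, seed = cfg$seed + 14,
                             relative = FALSE))
    if (!is.null(feats$hfa))
      pc$hfa <- percent_change(feats$hfa, tfr$times, dy$baseline,
                               dy$n_boot, seed = cfg$seed + 13)
    clusters <- list()
    if (!all(c("contra", "ipsi") %in% hand_cond)) {
      say("dynamics: only one hand condition present; contrast skipped")
    } else
    for (band in c("alpha", "beta")) {
      units <- res$select$selections[[band]]$selected %||% stim$name
      if (length(units) < 2) units <- stim$name  # cannot narrow: use all
      uidx <- match(units, stim$name)
      contra <- apply(pc[[band]][hand_cond == "contra", uidx, ,
                                 drop = FALSE], c(2, 3), mean)
      ipsi <- apply(pc[[band]][hand_cond == "ipsi", uidx, ,
                               drop = FALSE], c(2, 3), mean)
      clusters[[band]] <- cluster_permutation_test(
        contra, ipsi, n_perm = dy$n_perm, alpha = dy$alpha,
        times = tfr$times, seed = cfg$seed + 21)
    }
    res$dynamics <- list(tfr_times = tfr$times, features = feats,
                         percent_change = pc, clusters = clusters,
                         tfr = tfr, epochs_events = ep$events)
    if (length(clusters))
      say("dynamics: %d/%d significant alpha/beta clusters",
          nrow(significant_clusters(clusters$alpha) %||% data.frame()),
          nrow(significant_clusters(clusters$beta) %||% data.frame()))
    if (!is.null(out_dir)) {
      cl_tab <- do.call(rbind, lapply(names(clusters), function(nm) {
        cl <- clusters[[nm]]$clusters
        if (is.null(cl)) return(NULL)
        cbind(band = nm, cl)
      }))
      if (!is.null(cl_tab))
        write_stage_table(cl_tab, file.path(out_dir, "clusters.tsv"), cfg)
    }
  }

  ## --- waves ----------------------------------------------------------
  if (on_stage("waves") && !is.null(res$decompose)) {
    wv <- cfg$waves
    bands <- res$decompose$bands
    proj <- project_to_plane(rec$electrodes)
    n_use <- min(nrow(ev), wv$max_trials)
    use_tr <- round(seq(1, nrow(ev), length.out = n_use))
    waves <- list()
    for (bl in c("alpha", "beta")) {
      bb <- bands[bands$label == bl, ]
      ph_list <- vector("list", n_use)
      for (i in seq_along(use_tr)) {
        k <- use_tr[i]
        sig <- rec$signals[[ev$session[k]]]
        i0 <- round((ev$onset[k] + wv$window[1]) * fs) + 1
        i1 <- round((ev$onset[k] + wv$window[2]) * fs)
        filt <- bandpass(sig[i0:i1, , drop = FALSE], fs, bb$center,
                         max(bb$fwhm, 2))
        ph <- instantaneous_phase(filt)$phase
        ph_list[[i]] <- ph[seq(1, nrow(ph), by = wv$decimate), ,
                           drop = FALSE]
      }
      nt <- nrow(ph_list[[1]])
      grid <- plane_grid(proj$coords, 1)
      pgds <- dirs <- speeds <- vector("list", n_use)
      dir_arr <- array(NA_real_, c(n_use, nt, sum(grid$valid)))
      for (i in seq_len(n_use)) {
        g <- phase_gradient(ph_list[[i]], grid)
        pgds[[i]] <- pgd(g)
        dirs[[i]] <- wave_direction(g)
        speeds[[i]] <- wave_speed(bb$center, g)
        # per-site direction for DC
        th <- (atan2(-g$gy, -g$gx) * 180 / pi) %% 360
        dir_arr[i, , ] <- th[, grid$valid, drop = FALSE]
      }
      pooled_ph <- do.call(rbind, ph_list)
      nulls <- list(
        time = pgd_null(pooled_ph, proj, "time_shuffle", wv$n_perm,
                        seed = cfg$seed + 31),
        electrode = pgd_null(pooled_ph, proj, "electrode_shuffle",
                             wv$n_perm, seed = cfg$seed + 32))
      all_dirs <- unlist(dirs)
      waves[[bl]] <- list(
        band = bb, pgd = mean(unlist(pgds), na.rm = TRUE),
        pgd_null = nulls,
        directions = all_dirs,
        mean_direction = (circ_mean(all_dirs[!is.na(all_dirs)] * pi / 180) *
                            180 / pi) %% 360,
        speed = stats::median(unlist(speeds), na.rm = TRUE),
        rayleigh = rayleigh_test(all_dirs[!is.na(all_dirs)], degrees = TRUE),
        dc = directional_consistency(dir_arr),
        relative_phase = relative_phase_map(
          pooled_ph, which.min(rowSums(
            sweep(proj$coords, 2, colMeans(proj$coords))^2))))
      say("waves[%s]: PGD %.2f (p_time=%.3g, p_elec=%.3g), dir %.0f deg, %.1f cm/s",
          bl, waves[[bl]]$pgd, nulls$time$p, nulls$electrode$p,
          waves[[bl]]$mean_direction, waves[[bl]]$speed)
    }
    waves$kl <- direction_kl(waves$alpha$directions, waves$beta$directions,
                             cfg$waves$n_bins, n_perm = cfg$waves$n_perm,
                             seed = cfg$seed + 33)
    res$waves <- c(waves, list(projection = proj))
    say("waves: alpha-vs-beta direction KL %.3f (p=%.3g)",
        waves$kl$kl, waves$kl$p)
    if (!is.null(out_dir)) {
      wt <- data.frame(band = c("alpha", "beta"),
                       pgd = c(waves$alpha$pgd, waves$beta$pgd),
                       direction = c(waves$alpha$mean_direction,
                                     waves$beta$mean_direction),
                       speed_cm_s = c(waves$alpha$speed, waves$beta$speed),
                       rayleigh_p = c(waves$alpha$rayleigh$p,
                                      waves$beta$rayleigh$p))
      write_stage_table(wt, file.path(out_dir, "wave_metrics.tsv"), cfg)
    }
  }

  ## --- similarity -----------------------------------------------------
  if (on_stage("similarity") && !is.null(res$dynamics)) {
    # IRASA-corrected band envelopes (per-trial correlations are
    # invariant to per-channel affine scaling, so raw-vs-normalized
    # units do not matter here; the 1/f correction does)
    pcf <- res$dynamics$features
    times <- res$dynamics$tfr_times
    pairs <- utils::combn(names(pcf), 2, simplify = FALSE)
    sim_tab <- NULL
    rsms <- lapply(pcf, function(f) {
      n_tr <- dim(f)[1]
      pat <- matrix(f, n_tr, prod(dim(f)[-1]))
      build_rsm(pat)
    })
    for (pr in pairs) {
      rt <- temporal_correlation(pcf[[pr[1]]], pcf[[pr[2]]], times)
      rs <- spatial_correlation(pcf[[pr[1]]], pcf[[pr[2]]], times)
      rst <- spatiotemporal_correlation(pcf[[pr[1]]], pcf[[pr[2]]], times)
      rho <- rsa_second_order(rsms[[pr[1]]], rsms[[pr[2]]])
      sim_tab <- rbind(sim_tab, data.frame(
        featA = pr[1], featB = pr[2],
        r_temporal = mean(rt, na.rm = TRUE),
        r_spatial = mean(rs, na.rm = TRUE),
        r_spatiotemporal = mean(rst, na.rm = TRUE),
        rsa_rho = rho))
    }
    res$similarity <- list(table = sim_tab, rsms = rsms)
    say("similarity: alpha-beta temporal r = %.2f",
        sim_tab$r_temporal[sim_tab$featA == "alpha" &
                             sim_tab$featB == "beta"])
    if (!is.null(out_dir))
      write_stage_table(sim_tab, file.path(out_dir, "similarity.tsv"), cfg)
  }

  ## --- behavior -------------------------------------------------------
  if (on_stage("behavior") && "response" %in% names(ev)) {
    fits <- list()
    for (h in unique(ev$hand)) {
      sub <- ev[ev$hand == h, ]
      agg <- stats::aggregate(list(p = sub$response == "overhand"),
                              by = list(orientation = sub$orientation),
                              FUN = mean)
      fit <- fit_sine_psychometric(agg$orientation, agg$p)
      sw <- tryCatch(find_switch_points(fit),
                     ecog_no_switch_point = function(e) NULL)
      fits[[h]] <- list(fit = fit, switch_points = sw)
    }
    demand <- rep(NA_character_, nrow(ev))
    for (h in names(fits)) if (!is.null(fits[[h]]$switch_points))
      demand[ev$hand == h] <- label_demand(ev$orientation[ev$hand == h],
                                           fits[[h]]$switch_points,
                                           cfg$behavior$half_range)
    res$behavior <- list(fits = fits, demand = demand)
    say("behavior: R2 %s",
        paste(sprintf("%s=%.2f", names(fits),
                      vapply(fits, function(f) f$fit$r_squared, 0)),
              collapse = ", "))
    if (!is.null(out_dir)) {
      bj <- lapply(fits, function(f)
        list(a = f$fit$a, phi0 = f$fit$phi0, c = f$fit$c,
             r_squared = f$fit$r_squared, switch_points = f$switch_points))
      jsonlite::write_json(bj, file.path(out_dir, "behavior.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  ## --- report ---------------------------------------------------------
  if (on_stage("report") && !is.null(rec$ground_truth) &&
      !is.null(res$decompose)) {
    gt <- rec$ground_truth
    rep_tab <- list(
      slope_error = mean(res$decompose$features$slope) +
        gt$fractal_exponent,
      alpha_center_error =
        res$decompose$bands$center[res$decompose$bands$label == "alpha"] -
        gt$oscillations$alpha$center_freq,
      beta_center_error =
        res$decompose$bands$center[res$decompose$bands$label == "beta"] -
        gt$oscillations$beta$center_freq)
    if (!is.null(res$waves)) {
      proj <- res$waves$projection
      for (bl in c("alpha", "beta")) {
        d <- gt$oscillations[[bl]]$direction * pi / 180
        truth <- plane_azimuth(proj, c(cos(d), sin(d), 0))
        delta <- abs((res$waves[[bl]]$mean_direction - truth + 180) %%
                       360 - 180)
        rep_tab[[paste0(bl, "_direction_error_deg")]] <- delta
        rep_tab[[paste0(bl, "_speed_ratio")]] <-
          res$waves[[bl]]$speed / gt$oscillations[[bl]]$speed
      }
    }
    res$report <- rep_tab
    say("report: slope error %.3f", rep_tab$slope_error)
    if (!is.null(out_dir))
      jsonlite::write_json(rep_tab, file.path(out_dir, "recovery.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages: `run-all` executes every
#' stage; any single stage name runs the pipeline up to and including
#' that stage.  Flags: `--seed`, `--out`, `--trials`, `--sessions`.
#'
#' @param args character vector (default: command-line arguments).
#' @return the results bundle, invisibly.
#' @export
ecogwaves_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    args <- "run-all"
  cmd <- args[1]
  stages_all <- c("simulate", "decompose", "select", "dynamics", "waves",
                  "similarity", "behavior", "report")
  opt <- list(seed = 1L, out = NULL, trials = 60L, sessions = 2L)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- utils::type.convert(args[i + 1], as.is = TRUE)
    i <- i + 2
  }
  stages <- if (cmd == "run-all") stages_all else {
    if (!cmd %in% stages_all)
      stop_invalid(paste("unknown subcommand:", cmd))
    stages_all[seq_len(match(cmd, stages_all))]
  }
  cfg <- pipeline_config(
    seed = opt$seed, out_dir = opt$out, stages = stages,
    simulate = list(n_trials_per_session = opt$trials,
                    n_sessions = opt$sessions))
  run_pipeline(cfg)
}
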