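# Scripted validation protocols: classic cat-soleus stretch experiments run
# through the full spindle -> rate -> spiking-population pipeline, plus the
# spike-train statistics they require.

#' Instantaneous-frequency profile of a spike raster
#'
#' Per spike, instantaneous frequency is the reciprocal of the preceding
#' inter-spike interval. Profiles are aligned to trial onsets, held
#' piecewise-constant between spikes, and averaged across trials (and
#' neurons, if the raster has several).
#'
#' @param raster A [spike_raster()].
#' @param onsets_ms Trial onset times (ms).
#' @param window_ms Profile length after each onset (ms).
#' @return Data frame with `time_ms` (relative to onset), `freq_hz` and
#'   `n_profiles` (profiles contributing at each time); zero rows if no
#'   trial contains two spikes.
#' @export
instantaneous_frequency <- function(raster, onsets_ms, window_ms) {
  stopifnot(inherits(raster, "spike_raster"))
  grid <- seq_len(window_ms) - 1
  profiles <- list()
  for (onset in onsets_ms) {
    seg <- raster[raster$time_ms >= onset &
                    raster$time_ms < onset + window_ms, , drop = FALSE]
    for (id in unique(seg$neuron_id)) {
      st <- sort(seg$time_ms[seg$neuron_id == id]) - onset
      if (length(st) < 2) next
      isi <- diff(st)
      freq <- 1000 / isi            # ms -> Hz
      prof <- rep(NA_real_, window_ms)
      for (k in seq_along(freq)) {
        from <- floor(st[k + 1]) + 1
        to <- if (k < length(freq)) floor(st[k + 2]) else window_ms
        if (from <= to) prof[from:min(to, window_ms)] <- freq[k]
      }
      profiles[[length(profiles) + 1L]] <- prof
    }
  }
  acc <- do.call(rbind, profiles)
  if (is.null(acc)) {
    return(data.frame(time_ms = numeric(0), freq_hz = numeric(0),
                      n_profiles = integer(0)))
  }
  data.frame(time_ms = grid,
             freq_hz = colMeans(acc, na.rm = TRUE),
             n_profiles = colSums(!is.na(acc)))
}

#' Dynamic index of an afferent rate trace
#'
#' Classic phasic-sensitivity measure: the peak rate during the ramp minus
#' the rate probed a fixed delay (default 0.5 s) after the hold begins.
#'
#' @param time_ms,rate Rate trace on the ms grid.
#' @param ramp_window Two-element vector `(start_ms, end_ms)` of the ramp.
#' @param probe_delay_ms Delay of the hold probe after ramp end (ms).
#' @return Dynamic index (Hz).
#' @export
dynamic_index <- function(time_ms, rate, ramp_window,
                          probe_delay_ms = 500) {
  probe_t <- ramp_window[2] + probe_delay_ms
  if (ramp_window[1] < min(time_ms) || probe_t > max(time_ms)) {
    stop_domain("ramp window / hold probe lie outside the trace")
  }
  in_ramp <- time_ms >= ramp_window[1] & time_ms <= ramp_window[2]
  peak <- max(rate[in_ramp])
  hold <- rate[which.min(abs(time_ms - probe_t))]
  peak - hold
}

# Assemble one experiment result: rates, rasters, named stats.
.experiment_result <- function(wave, rates, rasters, stats) {
  structure(list(waveform = wave, rates = rates, rasters = rasters,
                 stats = stats),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result '%s': %d ms", x$waveform$label,
              nrow(x$rates)))
  if (length(x$rasters)) {
    cat(", rasters:", paste(names(x$rasters), collapse = "/"))
  }
  cat(">\n")
  if (length(x$stats)) {
    sc <- x$stats[vapply(x$stats, function(v) is.numeric(v) && length(v) == 1,
                         logical(1))]
    for (nm in names(sc)) cat(sprintf("  %s = %.4g\n", nm, sc[[nm]]))
  }
  invisible(x)
}

# Run the rate model plus both spiking populations for one condition.
.run_pipeline <- function(wave, gamma_dyn, gamma_stat, cfg, seed,
                          with_rasters = TRUE) {
  sp_cfg <- as_spindle_config(cfg)
  rates <- run_spindle(wave, gamma_dyn, gamma_stat, sp_cfg)
  rasters <- list()
  if (with_rasters) {
    gain <- .config_gain(cfg)
    rasters$ia <- run_population(rates$ia_rate, cfg$n_ia, "Ia",
                                 master_seed = seed, gain = gain,
                                 params = as_izhikevich_params(cfg),
                                 noise_amplitude_mv = cfg$noise_amplitude_mv)
    rasters$ii <- run_population(rates$ii_rate, cfg$n_ii, "II",
                                 master_seed = seed + 1L, gain = gain,
                                 params = as_izhikevich_params(cfg),
                                 noise_amplitude_mv = cfg$noise_amplitude_mv)
  }
  list(rates = rates, rasters = rasters)
}

# Pearson r between binned population counts and the binned rate trace.
.raster_rate_correlation <- function(raster, rate, bin_ms, n_neurons) {
  n_bins <- floor(length(rate) / bin_ms)
  if (n_bins < 3) stop_domain("trace too short for binning")
  counts <- bin_spike_counts(raster, bin_ms,
                             t_max_ms = n_bins * bin_ms)$count[seq_len(n_bins)]
  rate_bin <- colMeans(matrix(rate[seq_len(n_bins * bin_ms)],
                              nrow = bin_ms))
  if (stats::sd(counts) == 0 || stats::sd(rate_bin) == 0) {
    stop_domain("correlation undefined: zero-variance series")
  }
  ct <- stats::cor.test(counts, rate_bin, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = n_bins)
}

#' Ramp-and-hold stretch experiment (fusimotor drive off vs on)
#'
#' Runs the classic stretch-and-hold protocol (default 0.368 L0 over 200 ms)
#' through the spindle and both afferent populations twice: with zero gamma
#' drive ("ventral roots cut") and with tonic gamma drive on both fusimotor
#' inputs ("ventral roots intact"). The stats record the Ia and II dynamic
#' indices, mean rates, and the within-run consistency between the rasters
#' and the rate traces.
#'
#' @param config A [run_config()].
#' @param seed Master seed; defaults to the config's.
#' @return List of two `experiment_result`s, `cut` and `intact`.
#' @export
stretch_and_hold_experiment <- function(config = run_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$master_seed
  ex <- config$experiment
  wave <- ramp_hold(baseline = 1, amplitude = ex$ramp_amplitude,
                    ramp_ms = ex$ramp_ms, hold_ms = ex$hold_ms, pre_ms = 200)
  ramp_win <- c(200, 200 + ex$ramp_ms)
  conds <- list(cut = 0, intact = ex$tonic_gamma_hz)
  out <- lapply(names(conds), function(nm) {
    g <- conds[[nm]]
    run <- .run_pipeline(wave, g, g, config, seed)
    stats <- list(
      ia_dynamic_index = dynamic_index(run$rates$time_ms, run$rates$ia_rate,
                                       ramp_win),
      ii_dynamic_index = dynamic_index(run$rates$time_ms, run$rates$ii_rate,
                                       ramp_win),
      ia_mean = mean(run$rates$ia_rate),
      ii_mean = mean(run$rates$ii_rate),
      ia_consistency_r = .raster_rate_correlation(run$rasters$ia,
                                                  run$rates$ia_rate,
                                                  config$experiment$bin_ms,
                                                  config$n_ia)$r)
    .experiment_result(wave, run$rates, run$rasters, stats)
  })
  names(out) <- names(conds)
  out
}

#' Sinusoidal stretch with a fusimotor step (gamma dynamic vs static)
#'
#' A 3 Hz, 0.026 L0 peak-to-peak sinusoid; the selected gamma drive steps
#' from 0 to 80 Hz at the boundary between the 3rd and 4th cycle. Reports
#' per-cycle Ia modulation depth (max - min) and cycle-mean rate before the
#' step (cycles 1-3) and after it (cycle 5 onward, skipping the transition
#' cycle).
#'
#' @inheritParams stretch_and_hold_experiment
#' @return List of two `experiment_result`s, `dyn` and `stat`.
#' @export
fusimotor_sinusoid_experiment <- function(config = run_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$master_seed
  ex <- config$experiment
  wave <- sinusoid(baseline = 1, p2p = ex$sine_p2p, freq = ex$sine_freq_hz,
                   n_cycles = ex$sine_cycles)
  n <- length(wave$samples)
  cycle_ms <- 1000 / ex$sine_freq_hz
  step_at <- round(3 * cycle_ms)            # between the 3rd and 4th cycle
  gamma_step <- c(rep(0, step_at), rep(ex$gamma_step_hz, n - step_at))
  out <- lapply(c(dyn = "dyn", stat = "stat"), function(which) {
    gd <- if (which == "dyn") gamma_step else 0
    gs <- if (which == "stat") gamma_step else 0
    run <- .run_pipeline(wave, gd, gs, config, seed)
    cyc <- pmin(ex$sine_cycles,
                1 + floor(run$rates$time_ms / cycle_ms))
    depth <- tapply(run$rates$ia_rate, cyc, function(r) max(r) - min(r))
    cmean <- tapply(run$rates$ia_rate, cyc, mean)
    pre <- 1:3
    post <- 5:ex$sine_cycles
    stats <- list(
      depth_pre = mean(depth[pre]), depth_post = mean(depth[post]),
      mean_pre = mean(cmean[pre]), mean_post = mean(cmean[post]),
      depth_gain = mean(depth[post]) - mean(depth[pre]),
      mean_gain = mean(cmean[post]) - mean(cmean[pre]))
    .experiment_result(wave, run$rates, run$rasters, stats)
  })
  out
}

#' Four-waveform battery (linear stretch, tap, sinusoid, release)
#'
#' Runs the four classic stretch waveforms through the spindle and the
#' 128+128 neuron populations in the absence of fusimotor drive. The release
#' run's stats quantify the post-stop Ia burst (peak rate in the 100 ms after
#' the abrupt stop minus the rate just before it).
#'
#' @inheritParams stretch_and_hold_experiment
#' @return Named list of four `experiment_result`s: `linear`, `tap`,
#'   `sinusoid`, `release`.
#' @export
waveform_battery <- function(config = run_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$master_seed
  waves <- list(
    linear = ramp_hold(amplitude = 0.2, ramp_ms = 500, hold_ms = 500,
                       pre_ms = 200),
    tap = tap_pulse(),
    sinusoid = sinusoid(p2p = 0.05, freq = 2, n_cycles = 3, pre_ms = 200),
    release = release_ramp())
  out <- lapply(names(waves), function(nm) {
    run <- .run_pipeline(waves[[nm]], 0, 0, config, seed)
    stats <- list()
    if (nm == "release") {
      stop_ms <- 200 + 200                    # pre + ramp
      t <- run$rates$time_ms
      before <- run$rates$ia_rate[which.min(abs(t - (stop_ms - 5)))]
      after <- max(run$rates$ia_rate[t >= stop_ms & t <= stop_ms + 100])
      stats$post_stop_burst <- after - before
    }
    .experiment_result(waves[[nm]], run$rates, run$rasters, stats)
  })
  names(out) <- names(waves)
  out
}

#' Averaged instantaneous frequency under repeated triangular stretch
#'
#' Stretches the spindle with a repeated triangular waveform, drives a
#' single-afferent recording (first Ia neuron), and averages the
#' instantaneous-frequency profile across repetitions to expose the initial
#' burst at stretch onset.
#'
#' @inheritParams stretch_and_hold_experiment
#' @param n_reps Number of triangle repetitions.
#' @return An `experiment_result` whose stats hold the averaged profile and
#'   the early-peak / plateau contrast.
#' @export
triangular_burst_experiment <- function(config = run_config(), seed = NULL,
                                        n_reps = NULL) {
  if (is.null(seed)) seed <- config$master_seed
  if (is.null(n_reps)) n_reps <- config$experiment$triangle_reps
  wave <- triangular_wave(n_reps = n_reps)
  run <- .run_pipeline(wave, 0, 0, config, seed)
  onsets <- attr(wave, "onsets_ms")
  rise_ms <- 500
  rep_neuron <- run$rasters$ia[run$rasters$ia$neuron_id == 0L, , drop = FALSE]
  prof <- instantaneous_frequency(rep_neuron, onsets, rise_ms)
  early <- prof$freq_hz[prof$time_ms < 0.15 * rise_ms]
  mid <- prof$freq_hz[prof$time_ms >= 0.3 * rise_ms &
                        prof$time_ms < 0.9 * rise_ms]
  stats <- list(profile = prof,
                early_peak = if (length(early)) max(early, na.rm = TRUE) else NA_real_,
                mid_plateau = mean(mid, na.rm = TRUE))
  .experiment_result(wave, run$rates, run$rasters, stats)
}

#' White-noise encoding-fidelity experiment
#'
#' Stretches the spindle with low-pass filtered white noise (default 160 s,
#' 5 Hz cutoff), drives the Ia and II populations, bins the population spike
#' counts, and computes the Pearson correlation of each against the
#' rate-model output (with the standard t-test p-value).
#'
#' @inheritParams stretch_and_hold_experiment
#' @param with_rasters Keep the full rasters in the result (they are large).
#' @return List with `r_ia`, `r_ii`, `p_ia`, `p_ii`, `n_bins`, and `result`
#'   (an `experiment_result`).
#' @export
white_noise_correlation <- function(config = run_config(), seed = NULL,
                                    with_rasters = FALSE) {
  if (is.null(seed)) seed <- config$master_seed
  ex <- config$experiment
  wave <- filtered_white_noise(duration_s = ex$noise_duration_s,
                               cutoff_hz = ex$noise_cutoff_hz,
                               amplitude = ex$noise_amplitude_l0,
                               seed = seed)
  run <- .run_pipeline(wave, 0, 0, config, seed)
  cia <- .raster_rate_correlation(run$rasters$ia, run$rates$ia_rate,
                                  ex$bin_ms, config$n_ia)
  cii <- .raster_rate_correlation(run$rasters$ii, run$rates$ii_rate,
                                  ex$bin_ms, config$n_ii)
  stats <- list(r_ia = cia$r, p_ia = cia$p, r_ii = cii$r, p_ii = cii$p,
                n_bins = cia$n_bins)
  res <- .experiment_result(wave, run$rates,
                            if (with_rasters) run$rasters else list(), stats)
  list(r_ia = cia$r, r_ii = cii$r, p_ia = cia$p, p_ii = cii$p,
       n_bins = cia$n_bins, result = res)
}
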