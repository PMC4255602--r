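# Stretch-stimulus generators. All waveforms live on a uniform 1 ms grid and
# are expressed in units of resting muscle length (L0): L = 1 is the relaxed
# muscle, L = 1.368 a 36.8 % stretch.

#' Construct a muscle-length waveform
#'
#' @param samples Numeric vector of normalized lengths (L0 units), all > 0.
#' @param dt_ms Sample interval in ms (default 1, the emulation granularity).
#' @param label Protocol name.
#' @return An object of class `spindle_waveform`.
#' @export
waveform <- function(samples, dt_ms = 1, label = "custom") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop_domain("waveform needs at least one sample")
  if (any(!is.finite(samples)) || any(samples <= 0)) {
    stop_domain("waveform samples must be finite and > 0 (lengths in L0)")
  }
  if (!is.finite(dt_ms) || dt_ms <= 0) stop_domain("dt_ms must be > 0")
  structure(list(samples = samples, dt_ms = dt_ms, label = label),
            class = "spindle_waveform")
}

#' @export
print.spindle_waveform <- function(x, ...) {
  cat(sprintf("<spindle_waveform '%s': %d samples @ %g ms, L in [%.4f, %.4f] L0>\n",
              x$label, length(x$samples), x$dt_ms,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
as.data.frame.spindle_waveform <- function(x, ...) {
  data.frame(time_ms = (seq_along(x$samples) - 1) * x$dt_ms,
             length_l0 = x$samples)
}

#' Time axis of a waveform (ms)
#' @param w A `spindle_waveform`.
#' @export
waveform_time <- function(w) (seq_along(w$samples) - 1) * w$dt_ms

#' Fractional elongation relative to resting length
#'
#' Converts an absolute elongation into the normalized amplitude used by the
#' stimulus generators: e.g. a 14 mm stretch of a muscle whose rest length is
#' 38 mm is a fractional elongation of 0.368 (a stretch to 1.368 L0).
#'
#' @param elongation Absolute elongation (any length unit).
#' @param rest_length Resting muscle length (same unit).
#' @return Dimensionless fractional elongation (L0 units).
#' @export
normalized_elongation <- function(elongation, rest_length) {
  if (!is.finite(rest_length) || rest_length <= 0) {
    stop_domain("rest_length must be positive")
  }
  elongation / rest_length
}

#' Ramp-and-hold stretch
#'
#' Linear rise from `baseline` to `baseline + amplitude` over `ramp_ms`, then
#' held constant for `hold_ms`. The classic protocol uses a 0.368 L0 ramp over
#' 200 ms.
#'
#' @param baseline Starting length (L0), default 1.
#' @param amplitude Fractional elongation (L0), >= 0.
#' @param ramp_ms Ramp duration (ms).
#' @param hold_ms Hold duration (ms).
#' @param pre_ms Baseline padding before the ramp (ms).
#' @return A `spindle_waveform`.
#' @export
ramp_hold <- function(baseline = 1, amplitude = 0.368, ramp_ms = 200,
                      hold_ms = 1000, pre_ms = 200) {
  if (amplitude < 0) stop_domain("amplitude must be >= 0")
  if (ramp_ms <= 0 || hold_ms <= 0 || pre_ms < 0) {
    stop_domain("durations must be positive (pre_ms >= 0)")
  }
  t_pre  <- rep(baseline, pre_ms)
  t_ramp <- baseline + amplitude * (seq_len(ramp_ms) / ramp_ms)
  t_hold <- rep(baseline + amplitude, hold_ms)
  waveform(c(t_pre, t_ramp, t_hold), label = "ramp_hold")
}

#' Sinusoidal stretch
#'
#' Baseline-centered sine of the given peak-to-peak amplitude, starting at the
#' baseline with positive slope.
#'
#' @param baseline Center length (L0).
#' @param p2p Peak-to-peak amplitude (L0), >= 0.
#' @param freq Frequency (Hz), > 0.
#' @param n_cycles Number of cycles.
#' @param pre_ms Baseline padding before the sine (ms).
#' @return A `spindle_waveform`.
#' @export
sinusoid <- function(baseline = 1, p2p = 0.026, freq = 3, n_cycles = 8,
                     pre_ms = 0) {
  if (p2p < 0) stop_domain("p2p must be >= 0")
  if (freq <= 0) stop_domain("freq must be > 0")
  cycle_ms <- 1000 / freq
  n <- round(n_cycles * cycle_ms)
  t_s <- (seq_len(n) - 1) / 1000
  s <- baseline + (p2p / 2) * sin(2 * pi * freq * t_s)
  waveform(c(rep(baseline, pre_ms), s), label = "sinusoid")
}

#' Brief tap stimulus
#'
#' A raised-cosine bump of the given width; the tap shape itself is not
#' standardized in classic protocols, and a raised cosine avoids injecting
#' velocity discontinuities that are artifacts of the waveform rather than
#' the stimulus.
#'
#' @param baseline Baseline length (L0).
#' @param amplitude Bump height (L0), >= 0.
#' @param width_ms Bump width (ms).
#' @param pre_ms,post_ms Baseline padding around the bump (ms).
#' @return A `spindle_waveform`.
#' @export
tap_pulse <- function(baseline = 1, amplitude = 0.05, width_ms = 20,
                      pre_ms = 200, post_ms = 400) {
  if (amplitude < 0) stop_domain("amplitude must be >= 0")
  if (width_ms <= 0) stop_domain("width_ms must be > 0")
  ph <- seq_len(width_ms) / width_ms
  bump <- baseline + amplitude * 0.5 * (1 - cos(2 * pi * ph))
  waveform(c(rep(baseline, pre_ms), bump, rep(baseline, post_ms)),
           label = "tap")
}

#' Release (shortening) ramp with an abrupt stop
#'
#' Linear decrease by `drop` over `ramp_ms`, then constant. The velocity
#' discontinuity at the stop is deliberate: a sudden stop of shortening acts
#' on the spindle like a momentary stretch at very high velocity and evokes a
#' transient Ia burst.
#'
#' @param baseline Starting length (L0).
#' @param drop Fractional shortening (L0), must leave L > 0.
#' @param ramp_ms Release duration (ms).
#' @param pre_ms,post_ms Padding (ms).
#' @return A `spindle_waveform`.
#' @export
release_ramp <- function(baseline = 1.2, drop = 0.2, ramp_ms = 200,
                         pre_ms = 200, post_ms = 600) {
  if (drop < 0) stop_domain("drop must be >= 0")
  if (baseline - drop <= 0) stop_domain("release would make L <= 0")
  if (ramp_ms <= 0) stop_domain("ramp_ms must be > 0")
  ramp <- baseline - drop * (seq_len(ramp_ms) / ramp_ms)
  waveform(c(rep(baseline, pre_ms), ramp, rep(baseline - drop, post_ms)),
           label = "release")
}

#' Repeated triangular stretch
#'
#' Symmetric (by default) rise/fall triangles separated by a baseline
#' inter-trial interval, as used for averaged initial-burst measurements.
#'
#' @param baseline Baseline length (L0).
#' @param amplitude Peak elongation (L0), >= 0.
#' @param rise_ms,fall_ms Rise and fall durations (ms).
#' @param n_reps Number of repetitions.
#' @param iti_ms Inter-trial baseline interval (ms).
#' @return A `spindle_waveform` with attribute `onsets_ms` giving trial onsets.
#' @export
triangular_wave <- function(baseline = 1, amplitude = 0.1, rise_ms = 500,
                            fall_ms = 500, n_reps = 25, iti_ms = 500) {
  if (amplitude < 0) stop_domain("amplitude must be >= 0")
  if (rise_ms <= 0 || fall_ms <= 0 || iti_ms < 0) {
    stop_domain("durations must be positive (iti_ms >= 0)")
  }
  if (n_reps < 1) stop_domain("n_reps must be >= 1")
  one <- c(baseline + amplitude * (seq_len(rise_ms) / rise_ms),
           baseline + amplitude * ((fall_ms - seq_len(fall_ms)) / fall_ms),
           rep(baseline, iti_ms))
  w <- waveform(c(rep(baseline, iti_ms), rep(one, n_reps)),
                label = "triangular")
  attr(w, "onsets_ms") <- iti_ms + (seq_len(n_reps) - 1) * length(one)
  w
}

#' Low-pass filtered white-noise stretch
#'
#' Seeded pseudorandom samples low-pass filtered with a second-order
#' Butterworth filter applied forward and backward (zero phase), then rescaled
#' to span `[baseline, baseline + amplitude]`. Used for white-noise system
#' identification of the spindle-to-spike pathway.
#'
#' @param duration_s Duration (s), > 0.
#' @param cutoff_hz Low-pass cutoff (Hz), > 0 and below the grid Nyquist.
#' @param amplitude Span of the rescaled waveform (L0).
#' @param seed Integer seed; the waveform is a pure function of its arguments.
#' @param baseline Minimum length (L0).
#' @return A `spindle_waveform`.
#' @export
filtered_white_noise <- function(duration_s = 160, cutoff_hz = 5,
                                 amplitude = 0.1, seed = 1, baseline = 1) {
  if (duration_s <= 0) stop_domain("duration_s must be > 0")
  nyquist <- 500  # 1 ms grid
  if (cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    stop_domain("cutoff_hz must lie in (0, ", nyquist, ") Hz on the 1 ms grid")
  }
  if (amplitude < 0) stop_domain("amplitude must be >= 0")
  n <- round(duration_s * 1000)
  raw <- local_rng(seed, stats::rnorm(n))
  bf <- signal::butter(2, cutoff_hz / nyquist, type = "low")
  sm <- signal::filtfilt(bf, raw)
  rng <- range(sm)
  if (diff(rng) > 0) {
    sm <- (sm - rng[1]) / diff(rng) * amplitude + baseline
  } else {
    sm <- rep(baseline, n)
  }
  waveform(sm, label = "filtered_white_noise")
}

# Run `expr` under a temporarily seeded RNG, restoring global RNG state.
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
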