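# Rate-to-spike conversion: spindle firing rates become excitatory
# post-synaptic currents (EPSC) driving populations of Izhikevich Class-1
# neurons, each with an independent LFSR uniform noise stream on its membrane
# potential.

#' Izhikevich neuron parameters
#'
#' The membrane potential follows `dv/dt = k2 v^2 + k1 v + k0 - u + I` with
#' recovery `du/dt = a (b v - u)` and the peak/reset rule `v >= v_peak ->
#' v = c, u = u + d`. The default `"class1"` set gives Class-1 excitability
#' (firing rate rising continuously from zero with input current), the
#' property that makes a monotonic rate-to-current conversion possible; the
#' `"regular_spiking"` set is the common cortical alternative.
#'
#' @param preset `"class1"` (default) or `"regular_spiking"`.
#' @param ... Named overrides (`a`, `b`, `c`, `d`, `k2`, `k1`, `k0`,
#'   `v_peak`).
#' @return An object of class `izhikevich_params`.
#' @export
izhikevich_params <- function(preset = c("class1", "regular_spiking"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    class1 = list(a = 0.02, b = -0.1, c = -55, d = 6,
                  k2 = 0.04, k1 = 4.1, k0 = 108, v_peak = 30),
    regular_spiking = list(a = 0.02, b = 0.2, c = -65, d = 8,
                           k2 = 0.04, k1 = 5, k0 = 140, v_peak = 30))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop_config("unknown neuron parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(dots)] <- dots
  if (p$a <= 0) stop_config("a must be > 0")
  if (p$c >= p$v_peak) stop_config("reset c must be below v_peak")
  p$preset <- preset
  structure(p, class = "izhikevich_params")
}

#' Resting state of an Izhikevich neuron
#'
#' Solves the zero-input fixed point (`u = b v` on the membrane nullcline)
#' and returns the stable rest state.
#'
#' @param params An `izhikevich_params` object.
#' @return List with `v` (mV) and `u`.
#' @export
izhikevich_rest <- function(params) {
  # k2 v^2 + (k1 - b) v + k0 = 0; the more negative root is the stable node.
  disc <- (params$k1 - params$b)^2 - 4 * params$k2 * params$k0
  if (disc < 0) stop_config("neuron parameters have no resting state")
  v <- (-(params$k1 - params$b) - sqrt(disc)) / (2 * params$k2)
  list(v = v, u = params$b * v)
}

#' Rheobase current of an Izhikevich neuron
#'
#' Smallest constant current at which the rest/threshold fixed points merge
#' (saddle-node): above it the neuron fires repetitively.
#'
#' @param params An `izhikevich_params` object.
#' @return Current in model units.
#' @export
izhikevich_rheobase <- function(params) {
  (params$k1 - params$b)^2 / (4 * params$k2) - params$k0
}

#' One 1 ms Izhikevich update (reference implementation)
#'
#' Noise is added to the membrane potential, the membrane equation advances
#' in two half-steps (the standard stabilization of the quadratic model at
#' 1 ms), the recovery variable takes one full step, then the peak/reset rule
#' applies. The compiled population loop performs the identical update.
#'
#' @param state List with `v` (mV) and `u`.
#' @param I Input current (model units).
#' @param noise Membrane noise sample (mV) added this step.
#' @param dt Step (ms); the update is tuned for `dt = 1`.
#' @param params An `izhikevich_params` object.
#' @return List with `state` (advanced) and `spiked` (logical).
#' @export
izhikevich_step <- function(state, I, noise = 0, dt = 1,
                            params = izhikevich_params()) {
  if (dt <= 0) stop_domain("dt must be > 0")
  v <- state$v + noise
  u <- state$u
  half <- dt / 2
  v <- v + half * (params$k2 * v^2 + params$k1 * v + params$k0 - u + I)
  v <- v + half * (params$k2 * v^2 + params$k1 * v + params$k0 - u + I)
  u <- u + dt * params$a * (params$b * v - u)
  spiked <- FALSE
  if (!is.finite(v) || !is.finite(u)) {
    stop_numeric("non-finite neuron state")
  }
  if (v >= params$v_peak) {
    v <- params$c
    u <- u + params$d
    spiked <- TRUE
  }
  list(state = list(v = v, u = u), spiked = spiked)
}

#' Noise-free f-I curve
#'
#' Mean firing rate of a single neuron at each constant current, simulated
#' on the 1 ms grid.
#'
#' @param params An `izhikevich_params` object.
#' @param currents Numeric vector of input currents.
#' @param duration_ms Simulation length per current (ms).
#' @param discard_ms Initial transient to discard (ms).
#' @return Data frame with `current` and `rate_hz`.
#' @export
fi_curve <- function(params = izhikevich_params(),
                     currents = seq(0, 60, by = 1),
                     duration_ms = 3000, discard_ms = 500) {
  rest <- izhikevich_rest(params)
  pars <- .izh_par_vec(params)
  rate <- vapply(currents, function(I) {
    res <- run_izh_population_cpp(rep(I, duration_ms), 1L, 1L, 0,
                                  pars, rest$v, rest$u)
    sum(res$time_ms >= discard_ms) / ((duration_ms - discard_ms) / 1000)
  }, numeric(1))
  data.frame(current = currents, rate_hz = rate)
}

.izh_par_vec <- function(params) {
  as.numeric(params[c("a", "b", "c", "d", "k2", "k1", "k0", "v_peak")])
}

#' Calibrate the rate-to-current conversion
#'
#' Measures the noise-free f-I curve and inverts it so that a neuron driven
#' by `rate_to_epsc(r)` fires at about `r` Hz over the working range. The
#' inverse is stored as a monotone piecewise-linear interpolant anchored at
#' zero rate to a subthreshold current (slightly below rheobase), so a silent
#' spindle drives silent neurons. The f-I curve of a Class-1 neuron is
#' concave near threshold, so a monotone interpolant round-trips far better
#' than a straight-line fit.
#'
#' @param params An `izhikevich_params` object.
#' @param target_max_hz Upper end of the calibrated rate range (Hz), > 0.
#' @param n_points Number of f-I samples across the range.
#' @return An object of class `epsc_gain` (the gain_config consumed by
#'   [rate_to_epsc()]).
#' @export
calibrate_gain <- function(params = izhikevich_params(),
                           target_max_hz = 250, n_points = 40) {
  if (!is.finite(target_max_hz) || target_max_hz <= 0) {
    stop_config("target_max_hz must be > 0")
  }
  rheo <- izhikevich_rheobase(params)
  currents <- seq(rheo, rheo + 60, length.out = n_points)
  fi <- fi_curve(params, currents)
  keep <- fi$rate_hz > 0
  if (sum(keep) < 3) stop_config("f-I curve has too few firing points")
  f <- fi$rate_hz[keep]
  I <- fi$current[keep]
  if (any(diff(f) < 0)) {
    # enforce monotonicity: collapse any decreasing runs
    f <- cummax(f)
  }
  if (max(f) < target_max_hz) {
    # extend the sweep until the target rate is covered
    extra <- seq(max(I) + 2, max(I) + 400, by = 4)
    fi2 <- fi_curve(params, extra)
    f <- c(f, cummax(pmax(fi2$rate_hz, max(f))))
    I <- c(I, fi2$current)
    if (max(f) < target_max_hz) {
      stop_config("f-I curve does not reach target_max_hz = ", target_max_hz)
    }
  }
  dup <- duplicated(f)
  f <- f[!dup]; I <- I[!dup]
  # zero rate anchors 2 current units below rheobase: the +/-2.5 mV membrane
  # noise is worth about 1.75 units of equivalent current at rest, so a
  # silent spindle keeps its neurons silent even with noise on
  structure(list(rate_hz = c(0, f), current = c(rheo - 2, I),
                 rheobase = rheo, target_max_hz = target_max_hz,
                 preset = params$preset),
            class = "epsc_gain")
}

#' Convert a firing rate to an EPSC drive current
#'
#' Monotone non-decreasing mapping produced by [calibrate_gain()]. Zero rate
#' maps to a subthreshold current; rates above the calibrated range
#' extrapolate linearly from the last two calibration points.
#'
#' @param rate Firing rate (Hz), >= 0; vectorized.
#' @param gain An `epsc_gain` object.
#' @return Current (model units).
#' @export
rate_to_epsc <- function(rate, gain) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop_domain("rate must be finite and >= 0")
  }
  stopifnot(inherits(gain, "epsc_gain"))
  n <- length(gain$rate_hz)
  slope_hi <- (gain$current[n] - gain$current[n - 1]) /
    (gain$rate_hz[n] - gain$rate_hz[n - 1])
  out <- stats::approx(gain$rate_hz, gain$current, xout = pmin(rate, gain$rate_hz[n]),
                       rule = 2)$y
  over <- rate > gain$rate_hz[n]
  if (any(over)) {
    out[over] <- gain$current[n] + slope_hi * (rate[over] - gain$rate_hz[n])
  }
  out
}

#' LFSR noise stream
#'
#' 32-bit maximal-length Galois linear-feedback shift register (taps 32, 22,
#' 2, 1) producing uniform samples on `[-amplitude/2, +amplitude/2]` mV; the
#' hardware-style membrane noise source. The default 5 mV amplitude is read
#' as peak-to-peak (samples on +/- 2.5 mV).
#'
#' @param seed Nonzero 32-bit integer register seed.
#' @param amplitude_mv Peak-to-peak amplitude (mV).
#' @return An object of class `noise_stream`.
#' @export
noise_stream <- function(seed, amplitude_mv = 5) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed == 0L) stop_domain("LFSR seed must be nonzero")
  if (amplitude_mv < 0) stop_domain("amplitude_mv must be >= 0")
  structure(list(lfsr_state = seed, amplitude = amplitude_mv),
            class = "noise_stream")
}

#' Draw samples from an LFSR noise stream
#'
#' @param stream A `noise_stream`.
#' @param n Number of samples.
#' @return List with `samples` (mV) and the advanced `stream`.
#' @export
lfsr_noise <- function(stream, n = 1) {
  stopifnot(inherits(stream, "noise_stream"))
  res <- lfsr_sequence_cpp(stream$lfsr_state, as.integer(n),
                           stream$amplitude)
  st <- res$state
  # re-pack the unsigned register value into a signed R integer
  if (st >= 2^31) st <- st - 2^32
  stream$lfsr_state <- as.integer(st)
  list(samples = res$samples, stream = stream)
}

#' Spike raster container
#'
#' @param time_ms Spike times (ms), non-decreasing within each neuron.
#' @param neuron_id Zero-based neuron indices.
#' @param n_neurons Population size.
#' @param group `"Ia"` or `"II"`.
#' @return An object of class `spike_raster` (a data.frame with attributes).
#' @export
spike_raster <- function(time_ms, neuron_id, n_neurons, group = "Ia") {
  if (length(time_ms) != length(neuron_id)) {
    stop_domain("time_ms and neuron_id must have equal length")
  }
  if (length(neuron_id) && (min(neuron_id) < 0 || max(neuron_id) >= n_neurons)) {
    stop_domain("neuron_id must lie in [0, n_neurons)")
  }
  if (length(time_ms)) {
    o <- order(neuron_id, time_ms)
    dec <- tapply(time_ms, neuron_id, function(t) any(diff(t) < 0))
    if (any(unlist(dec))) {
      stop_domain("spike times must be non-decreasing within each neuron")
    }
    rm(o)
  }
  structure(data.frame(time_ms = time_ms, neuron_id = as.integer(neuron_id)),
            n_neurons = as.integer(n_neurons), group = group,
            class = c("spike_raster", "data.frame"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster: %d spikes, %d %s neurons, t in [%s, %s] ms>\n",
              nrow(x), attr(x, "n_neurons"), attr(x, "group"),
              if (nrow(x)) format(min(x$time_ms)) else "-",
              if (nrow(x)) format(max(x$time_ms)) else "-"))
  invisible(x)
}

# Derive independent, nonzero per-neuron LFSR seeds from one master seed.
.neuron_seeds <- function(master_seed, n) {
  local_rng(master_seed, sample.int(.Machine$integer.max, n))
}

#' Drive a neuron population with a rate trace
#'
#' Every neuron receives the same EPSC timeline (the rate trace passed
#' through [rate_to_epsc()]) plus an independent LFSR membrane-noise stream
#' seeded from `master_seed`. Bit-reproducible for a fixed
#' (configuration, master_seed) pair.
#'
#' @param rate_trace Firing-rate time series (Hz) on the 1 ms grid.
#' @param n_neurons Population size (> 0).
#' @param group Afferent group label (`"Ia"` or `"II"`).
#' @param master_seed Integer master seed for the per-neuron noise streams.
#' @param gain An `epsc_gain` from [calibrate_gain()].
#' @param params An `izhikevich_params` object.
#' @param noise_amplitude_mv Peak-to-peak membrane noise (mV).
#' @return A [spike_raster()].
#' @export
run_population <- function(rate_trace, n_neurons = 128, group = "Ia",
                           master_seed = 1, gain = NULL,
                           params = izhikevich_params(),
                           noise_amplitude_mv = 5) {
  if (n_neurons <= 0) stop_config("n_neurons must be > 0")
  if (is.null(gain)) gain <- calibrate_gain(params)
  epsc <- rate_to_epsc(rate_trace, gain)
  rest <- izhikevich_rest(params)
  seeds <- .neuron_seeds(master_seed, n_neurons)
  res <- run_izh_population_cpp(epsc, as.integer(n_neurons),
                                as.integer(seeds), noise_amplitude_mv,
                                .izh_par_vec(params), rest$v, rest$u)
  spike_raster(res$time_ms, res$neuron_id, n_neurons, group)
}

#' Bin population spike counts
#'
#' @param raster A `spike_raster`.
#' @param bin_ms Bin width (ms).
#' @param t_max_ms Trace length (ms); defaults to the last spike time.
#' @return Data frame with `time_ms` (bin start) and `count`.
#' @export
bin_spike_counts <- function(raster, bin_ms = 20, t_max_ms = NULL) {
  if (is.null(t_max_ms)) t_max_ms <- if (nrow(raster)) max(raster$time_ms) + 1 else bin_ms
  breaks <- seq(0, ceiling(t_max_ms / bin_ms) * bin_ms, by = bin_ms)
  cnt <- if (nrow(raster)) {
    tabulate(findInterval(raster$time_ms, breaks, left.open = FALSE),
             nbins = length(breaks) - 1)
  } else {
    integer(length(breaks) - 1)
  }
  data.frame(time_ms = breaks[-length(breaks)], count = cnt)
}
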