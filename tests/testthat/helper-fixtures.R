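# Shared fixtures: small population sizes keep the unit suites fast; the
# acceptance suite uses the full default configuration.

small_config <- function(...) {
  run_config(n_ia = 16, n_ii = 16, ...)
}

# One calibration shared across tests (deterministic).
test_gain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_gain(izhikevich_params(), 250)
    cache
  }
})

# Log-uniform sample on [1e-6, 1e6], fixed seed.
log_uniform_sweep <- function(n, seed = 42) {
  set.seed(seed)
  10^stats::runif(n, -6, 6)
}

# Synthetic raster with exactly periodic spikes for every neuron.
periodic_raster <- function(isi_ms = 10, n_spikes = 50, n_neurons = 1) {
  t <- rep(seq_len(n_spikes) * isi_ms, n_neurons)
  id <- rep(seq_len(n_neurons) - 1L, each = n_spikes)
  spike_raster(t, id, n_neurons, "Ia")
}
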