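test_that("instantaneous frequency of a periodic train is flat at 1/ISI", {
  ras <- periodic_raster(isi_ms = 10, n_spikes = 50)
  prof <- instantaneous_frequency(ras, onsets_ms = 0, window_ms = 500)
  expect_equal(unique(prof$freq_hz[!is.nan(prof$freq_hz)]), 100)
  # a single spike per trial yields no profile
  one <- spike_raster(5, 0L, 1)
  empty <- instantaneous_frequency(one, onsets_ms = 0, window_ms = 100)
  expect_identical(nrow(empty), 0L)
})

test_that("instantaneous frequency averages across aligned trials", {
  # two trials, ISIs of 10 ms and 20 ms -> mean of 100 and 50 Hz
  t <- c(seq(10, 90, by = 10), 200 + seq(20, 180, by = 20))
  ras <- spike_raster(t, rep(0L, length(t)), 1)
  prof <- instantaneous_frequency(ras, onsets_ms = c(0, 200), window_ms = 100)
  mid <- prof$freq_hz[prof$time_ms == 50]
  expect_equal(mid, mean(c(100, 50)))
})

test_that("dynamic index subtracts the hold rate from the ramp peak", {
  t <- 0:1500
  expect_equal(dynamic_index(t, rep(30, length(t)), c(200, 400)), 0)
  rate <- rep(30, length(t))
  rate[t >= 200 & t <= 400] <- 80
  expect_equal(dynamic_index(t, rate, c(200, 400)), 50)
  expect_error(dynamic_index(t, rate, c(1300, 1400)),
               class = "spindlesim_domain_error")
})

test_that("ramp-and-hold experiment differentiates Ia from II and gamma on from off", {
  cfg <- small_config(experiment = list(hold_ms = 800))
  res <- stretch_and_hold_experiment(cfg)
  expect_gt(res$cut$stats$ia_dynamic_index, res$cut$stats$ii_dynamic_index)
  expect_gt(res$cut$stats$ii_dynamic_index, 0)
  expect_gt(res$intact$stats$ia_mean, res$cut$stats$ia_mean)
  expect_gt(res$intact$stats$ii_mean, res$cut$stats$ii_mean)
  # rasters track the rate traces within the run
  expect_gt(res$cut$stats$ia_consistency_r, 0.7)
})

test_that("gamma dynamic boosts modulation depth; gamma static the mean rate", {
  cfg <- small_config()
  res <- fusimotor_sinusoid_experiment(cfg)
  expect_gt(res$dyn$stats$depth_gain, 0)
  expect_gt(res$stat$stats$mean_gain, 0)
  expect_gt(res$stat$stats$mean_gain, res$dyn$stats$mean_gain)
  # identical stimulus and seed before the step -> identical rates
  pre <- res$dyn$rates$time_ms < 1000
  expect_identical(res$dyn$rates$ia_rate[pre], res$stat$rates$ia_rate[pre])
})

test_that("the waveform battery reproduces the release burst", {
  cfg <- small_config()
  res <- waveform_battery(cfg)
  expect_named(res, c("linear", "tap", "sinusoid", "release"))
  expect_gt(res$release$stats$post_stop_burst, 0)
  # ensemble counts track the rate model within each run
  r <- spindlesim:::.raster_rate_correlation(res$linear$rasters$ia,
                                             res$linear$rates$ia_rate, 20, 16)
  expect_gt(r$r, 0.7)
})

test_that("triangular stretch shows an initial burst in averaged frequency", {
  cfg <- small_config()
  res <- triangular_burst_experiment(cfg, n_reps = 8)
  expect_gt(res$stats$early_peak, res$stats$mid_plateau)
})

test_that("white-noise correlation is seeded and rejects degenerate input", {
  cfg <- small_config(experiment = list(noise_duration_s = 10))
  a <- white_noise_correlation(cfg, seed = 3)
  b <- white_noise_correlation(cfg, seed = 3)
  expect_identical(a$r_ia, b$r_ia)
  expect_gt(a$r_ia, 0.5)
  expect_gt(a$r_ii, 0.5)
  expect_lt(a$p_ia, 1e-4)
  # constant stimulus -> zero-variance rate trace -> undefined correlation
  flat <- ramp_hold(amplitude = 0, ramp_ms = 10, hold_ms = 3000, pre_ms = 0)
  rates <- run_spindle(flat)
  ras <- run_population(rates$ia_rate, 4, master_seed = 1, gain = test_gain())
  expect_error(
    spindlesim:::.raster_rate_correlation(ras, rates$ia_rate, 20, 4),
    class = "spindlesim_domain_error")
})

test_that("experiments are reproducible given config and seed", {
  cfg <- small_config(experiment = list(hold_ms = 600))
  a <- stretch_and_hold_experiment(cfg, seed = 11)
  b <- stretch_and_hold_experiment(cfg, seed = 11)
  expect_identical(a$cut$rates, b$cut$rates)
  expect_identical(as.data.frame(a$cut$rasters$ia),
                   as.data.frame(b$cut$rasters$ia))
})
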