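bag1 <- fiber_parameters("bag1")

test_that("fusimotor activation dynamics match the saturating form", {
  expect_equal(fusimotor_activation_derivative(0, 0, bag1), 0)
  expect_equal(fusimotor_activation_derivative(0, bag1$omega, bag1),
               0.5 / bag1$tau)
  # independent evaluation: gamma = 80, omega = 60, tau = 0.149
  expect_equal(fusimotor_activation_derivative(0.2, 80, bag1),
               (6400 / (6400 + 3600) - 0.2) / 0.149)
  expect_error(fusimotor_activation_derivative(0, -1, bag1),
               class = "spindlesim_domain_error")
})

test_that("intrafusal tensions match hand evaluation", {
  st <- fiber_state(x0 = 0.3, x1 = 0.95, x2 = 0.5)
  tens <- intrafusal_tensions(st, L = 1.05, bag1)
  expect_equal(tens$t_sr, 10.4649 * (1.05 - 0.95 - 0.04))
  expect_equal(tens$t_pr, 0.15 * (0.95 - 0.76))
  expect_equal(tens$t_b,
               (0.0605 + 0.2592 * 0.3) * (0.95 - 0.46) * 1 * 0.5^0.3)
  # spring at rest length and zero-velocity damping
  st0 <- fiber_state(x1 = 1.05 - bag1$l0_sr, x2 = 0)
  expect_equal(intrafusal_tensions(st0, 1.05, bag1)$t_sr, 0)
  expect_equal(intrafusal_tensions(st0, 1.05, bag1)$t_b, 0)
  # shortening uses the asymmetric damping coefficient
  stm <- fiber_state(x0 = 0.3, x1 = 0.95, x2 = -0.5)
  expect_equal(intrafusal_tensions(stm, 1.05, bag1)$t_b,
               -(0.0605 + 0.2592 * 0.3) * (0.95 - 0.46) * 0.42 * 0.5^0.3)
})

test_that("fiber derivatives chain tensions through Newton's law", {
  st <- fiber_state(x0 = 0.3, x1 = 0.95, x2 = 0.5)
  inp <- spindle_input(1.05, gamma_dyn = 80)
  d <- fiber_derivatives(st, inp, bag1)
  expect_identical(d$dx1, st$x2)
  t_sr <- 10.4649 * 0.06
  t_pr <- 0.15 * 0.19
  t_b <- (0.0605 + 0.2592 * 0.3) * 0.49 * 0.5^0.3
  expect_equal(d$dx2, (t_sr - t_b - t_pr - 0.0289 * 0.3) / 2e-4)
  expect_equal(d$dx0, (0.64 - 0.3) / 0.149)
})

test_that("equilibrium states are fixed points of the dynamics", {
  for (gd in c(0, 50)) {
    inp <- spindle_input(1.1, gamma_dyn = gd, gamma_stat = gd)
    eq <- spindle_equilibrium(inp)
    cfg <- spindle_config()
    for (nm in c("bag1", "bag2", "chain")) {
      d <- fiber_derivatives(eq[[nm]], inp, cfg$fibers[[nm]])
      expect_equal(d$dx0, 0, tolerance = 1e-10)
      expect_equal(d$dx1, 0)
      expect_equal(d$dx2, 0, tolerance = 1e-7)
    }
  }
})

test_that("one integrator substep matches the hand-computed update", {
  st <- fiber_state(x0 = 0.3, x1 = 0.95, x2 = 0.5)
  inp <- spindle_input(1.05, gamma_dyn = 80)
  d <- fiber_derivatives(st, inp, bag1)
  new <- step_fiber(st, inp, bag1, dt = 0.001, substeps = 1)
  x2_new <- st$x2 + 0.001 * d$dx2
  expect_equal(new$x0, st$x0 + 0.001 * d$dx0)
  expect_equal(new$x2, x2_new)
  expect_equal(new$x1, st$x1 + 0.001 * x2_new)  # position from new velocity
  expect_error(step_fiber(st, inp, bag1, dt = 0),
               class = "spindlesim_domain_error")
})

test_that("a fiber relaxes to equilibrium under constant input", {
  inp <- spindle_input(1.2, gamma_dyn = 0)
  st <- fiber_state(x0 = 0, x1 = 1.0, x2 = 0)   # perturbed start
  for (i in 1:2000) st <- step_fiber(st, inp, bag1)
  expect_lt(abs(st$x2), 5e-4)
  eq <- spindle_equilibrium(inp)$bag1
  expect_lt(abs(st$x1 - eq$x1), 5e-4)
})

test_that("integration failure is reported as a numerical error", {
  stiff <- fiber_parameters("bag1", m = 1e-9)
  st <- fiber_state(x0 = 0, x1 = 1.0, x2 = 0)
  expect_error(step_fiber(st, spindle_input(1.2), stiff, dt = 0.1,
                          substeps = 1000),
               class = "spindlesim_numeric_error")
})

test_that("afferent combination applies partial occlusion", {
  z <- combine_afferents(0, 0, 0, 0, 0)
  expect_equal(z$ia_rate, 0)
  expect_equal(z$ii_rate, 0)
  only_b1 <- combine_afferents(40, 0, 0, 0, 0)
  expect_equal(only_b1$ia_rate, 40)
  expect_equal(only_b1$ii_rate, 0)
  mixed <- combine_afferents(40, 30, 20, 10, 5, occlusion_factor = 0.156)
  expect_equal(mixed$ia_rate, 50 + 0.156 * 40)
  expect_equal(mixed$ii_rate, 15)
})

test_that("a spindle at constant length settles to constant baseline rates", {
  inp <- spindle_input(1.0)
  st <- spindle_equilibrium(inp)
  cfg <- spindle_config()
  first <- step_spindle(st, inp, config = cfg)
  last <- first
  for (i in 1:200) last <- step_spindle(last$state, inp, config = cfg)
  expect_equal(last$rates$ia_rate, first$rates$ia_rate, tolerance = 1e-4)
  expect_equal(last$rates$ii_rate, first$rates$ii_rate, tolerance = 1e-4)
})

test_that("compiled and reference integrators agree", {
  w <- ramp_hold(amplitude = 0.368, ramp_ms = 100, hold_ms = 200, pre_ms = 20)
  for (mode in c("exact", "fpga_faithful")) {
    cfg <- spindle_config(mode)
    rc <- run_spindle(w, 30, 30, cfg, engine = "cpp")
    rr <- run_spindle(w, 30, 30, cfg, engine = "r")
    tol <- if (mode == "exact") 1e-8 else 1.5  # float datapaths may differ in
    expect_lt(max(abs(rc$ia_rate - rr$ia_rate)), tol)   # the last rounding
    expect_lt(max(abs(rc$ii_rate - rr$ii_rate)), tol)
  }
})

test_that("afferent rates are nonnegative for arbitrary stimuli", {
  set.seed(21)
  for (i in 1:5) {
    w <- waveform(pmax(0.2, 1 + cumsum(stats::rnorm(400, 0, 0.01))))
    r <- run_spindle(w, stats::runif(1, 0, 100), stats::runif(1, 0, 100))
    expect_true(all(r$ia_rate >= 0))
    expect_true(all(r$ii_rate >= 0))
  }
})

test_that("ramp responses are phasic for Ia and velocity-sensitive", {
  peaks <- vapply(c(400, 200, 100), function(rms) {
    w <- ramp_hold(amplitude = 0.368, ramp_ms = rms, hold_ms = 600,
                   pre_ms = 100)
    r <- run_spindle(w)
    max(r$ia_rate[r$time_ms <= 100 + rms + 50])
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))  # faster ramp, higher Ia peak

  w <- ramp_hold(amplitude = 0.368, ramp_ms = 200, hold_ms = 800,
                 pre_ms = 100)
  r0 <- run_spindle(w, 0, 0)
  peak <- max(r0$ia_rate[r0$time_ms <= 300])
  hold <- r0$ia_rate[r0$time_ms == 800]
  expect_gt(peak, hold)
  # tonic fusimotor drive facilitates both groups throughout
  r50 <- run_spindle(w, 50, 50)
  expect_true(all(r50$ia_rate >= r0$ia_rate - 1e-9))
  expect_true(all(r50$ii_rate >= r0$ii_rate - 1e-9))
})

test_that("fiber parameter and config validation name the offending key", {
  expect_error(fiber_parameters("bag1", tau = -1), "tau",
               class = "spindlesim_config_error")
  expect_error(fiber_parameters("bag1", nosuch = 1),
               class = "spindlesim_config_error")
  expect_error(spindle_config(occlusion_factor = 2),
               class = "spindlesim_config_error")
  expect_error(spindle_input(-1), class = "spindlesim_domain_error")
  expect_error(fiber_state(x0 = 2), class = "spindlesim_domain_error")
})
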