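# Three-fiber spindle model: bag1, bag2 and nuclear chain intrafusal fibers,
# each a second-order spring/damper sandwich (sensory region in series with a
# contractile polar region), driven by muscle length L and gamma fusimotor
# rates. Group Ia and II firing rates are read out from the sensory-region
# stretch. State per fiber:
#   x0 - fusimotor activation (0..1)
#   x1 - polar-region length (L0)
#   x2 - polar-region velocity (L0/s)

#' Intrafusal fiber parameters
#'
#' Returns the constants of one intrafusal fiber. The defaults are the cat
#' soleus values of the rate-based spindle model this emulator implements;
#' lengths are in units of resting muscle length (L0), forces in model force
#' units (FU), so spring constants are FU/L0 and damping FU.s/L0.
#'
#' Fusimotor routing follows the standard spindle architecture: bag1 is driven
#' by gamma dynamic, bag2 and chain by gamma static. The activation-scaled
#' damping coefficient `b1` is positive for bag1 (dynamic drive raises
#' velocity sensitivity) and negative for bag2/chain (static drive slightly
#' reduces damping while adding contractile bias force `gamma_force * x0`).
#'
#' @param fiber One of `"bag1"`, `"bag2"`, `"chain"`.
#' @param ... Named overrides of individual constants.
#' @return An object of class `fiber_parameters`.
#' @export
fiber_parameters <- function(fiber = c("bag1", "bag2", "chain"), ...) {
  fiber <- match.arg(fiber)
  base <- list(
    k_sr = 10.4649,   # sensory-region spring constant (FU/L0)
    k_pr = 0.15,      # polar-region spring constant (FU/L0)
    m = 2e-4,         # polar-region mass term (FU.s^2/L0)
    l0_sr = 0.04,     # sensory-region rest length (L0)
    l0_pr = 0.76,     # polar-region rest length (L0)
    l_n_sr = 0.0423,  # sensory-region threshold length for afferent firing
    l_n_pr = 0.89,    # polar-region threshold length (secondary ending)
    r_damp = 0.46,    # damping length offset (L0)
    a_exp = 0.3,      # velocity exponent of the damping term
    c_lengthen = 1,   # velocity-sign asymmetry (polar region lengthening)
    c_shorten = 0.42, # ... and shortening
    p = 2,            # fusimotor saturation exponent
    omega = 60,       # half-activation fusimotor rate (Hz)
    tau = 0.149,      # activation time constant (s)
    b0 = 0.0605,      # passive damping coefficient (FU.s/L0)
    b1 = 0.2592,      # activation-scaled damping coefficient
    gamma_force = 0.0289, # fusimotor contractile force scaling (FU)
    g_primary = 20000,    # Ia gain (Hz per L0 of suprathreshold SR stretch)
    g_secondary = 0,      # II gain (bag1 contributes nothing to II)
    x_sec = 0.7,      # fraction of the secondary ending on the sensory region
    l_sec = 0.04      # secondary-ending length (L0)
  )
  if (fiber == "bag2") {
    base[c("tau", "b0", "b1", "gamma_force", "g_primary", "g_secondary")] <-
      list(0.205, 0.0822, -0.046, 0.0636, 10000, 7250)
  } else if (fiber == "chain") {
    # The chain fiber has no slow activation dynamics; a very small tau makes
    # activation effectively instantaneous on the 1 ms grid.
    base[c("tau", "omega", "b0", "b1", "gamma_force",
           "g_primary", "g_secondary", "m")] <-
      list(0.001, 90, 0.0822, -0.069, 0.0954, 10000, 7250, 1e-4)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown)) {
    stop_config("unknown fiber parameter(s): ", paste(unknown, collapse = ", "))
  }
  base[names(dots)] <- dots
  base$fiber <- fiber
  .validate_fiber_params(base)
  structure(base, class = "fiber_parameters")
}

.validate_fiber_params <- function(p) {
  if (p$m <= 0) stop_config("fiber ", p$fiber, ": m must be > 0")
  if (p$tau <= 0) stop_config("fiber ", p$fiber, ": tau must be > 0")
  for (f in c("k_sr", "k_pr", "g_primary")) {
    if (p[[f]] < 0) stop_config("fiber ", p$fiber, ": ", f, " must be >= 0")
  }
  if (p$k_sr <= 0) stop_config("fiber ", p$fiber, ": k_sr must be > 0")
  invisible(p)
}

#' Intrafusal fiber state
#'
#' @param x0 Fusimotor activation, in `[0, 1]`.
#' @param x1 Polar-region length (L0).
#' @param x2 Polar-region velocity (L0/s).
#' @return An object of class `fiber_state`.
#' @export
fiber_state <- function(x0 = 0, x1 = 0.95, x2 = 0) {
  if (!all(is.finite(c(x0, x1, x2)))) stop_domain("fiber state must be finite")
  if (x0 < 0 || x0 > 1) stop_domain("x0 must lie in [0, 1]")
  structure(list(x0 = x0, x1 = x1, x2 = x2), class = "fiber_state")
}

#' Spindle input sample
#'
#' @param L Muscle length (L0), > 0.
#' @param gamma_dyn Gamma dynamic fusimotor rate (Hz, >= 0).
#' @param gamma_stat Gamma static fusimotor rate (Hz, >= 0).
#' @export
spindle_input <- function(L, gamma_dyn = 0, gamma_stat = 0) {
  if (!is.finite(L) || L <= 0) stop_domain("L must be finite and > 0")
  if (gamma_dyn < 0 || gamma_stat < 0) stop_domain("gamma rates must be >= 0")
  structure(list(L = L, gamma_dyn = gamma_dyn, gamma_stat = gamma_stat),
            class = "spindle_input")
}

# Gamma rate seen by one fiber under the standard routing.
.fiber_gamma <- function(params, input) {
  if (params$fiber == "bag1") input$gamma_dyn else input$gamma_stat
}

#' Fusimotor activation dynamics
#'
#' First-order saturating activation:
#' `dx0/dt = (gamma^p / (gamma^p + omega^p) - x0) / tau` with `p = 2`.
#' At `gamma = omega` the steady-state activation is 0.5.
#'
#' @param x0 Current activation.
#' @param gamma Fusimotor rate (Hz, >= 0).
#' @param params A `fiber_parameters` object.
#' @return dx0/dt (1/s).
#' @export
fusimotor_activation_derivative <- function(x0, gamma, params) {
  if (gamma < 0) stop_domain("gamma must be >= 0")
  if (params$tau <= 0) stop_config("tau must be > 0")
  gp <- gamma^params$p
  ss <- if (gp == 0) 0 else gp / (gp + params$omega^params$p)
  (ss - x0) / params$tau
}

# Steady-state activation for a constant gamma rate.
.activation_ss <- function(gamma, params) {
  gp <- gamma^params$p
  if (gp == 0) 0 else gp / (gp + params$omega^params$p)
}

#' Tension components of one intrafusal fiber
#'
#' Sensory-region spring tension `T_SR = k_sr (L - x1 - l0_sr)`, polar-region
#' spring tension `T_PR = k_pr (x1 - l0_pr)`, and the nonlinear damping
#' tension `T_B = (b0 + b1 x0) (x1 - r_damp) C(x2) sign(x2) |x2|^a_exp`,
#' where `C` is the lengthening/shortening asymmetry coefficient. In
#' `fpga_faithful` mode the velocity power uses the quarter-power
#' approximation (`a_exp = 0.25`) built from the fast inverse square root and
#' all products are rounded to single precision.
#'
#' @param state A `fiber_state`.
#' @param L Muscle length (L0).
#' @param params A `fiber_parameters` object.
#' @param arith `"exact"` or `"fpga_faithful"`.
#' @param a_exp Velocity exponent; defaults to `params$a_exp` in exact mode
#'   and 0.25 in fpga_faithful mode.
#' @return Named list with `t_sr`, `t_b`, `t_pr` (FU).
#' @export
intrafusal_tensions <- function(state, L, params,
                                arith = c("exact", "fpga_faithful"),
                                a_exp = NULL) {
  arith <- match.arg(arith)
  if (is.null(a_exp)) a_exp <- if (arith == "exact") params$a_exp else 0.25
  c_ss <- if (state$x2 < 0) params$c_shorten else params$c_lengthen
  if (arith == "exact") {
    t_sr <- params$k_sr * (L - state$x1 - params$l0_sr)
    t_pr <- params$k_pr * (state$x1 - params$l0_pr)
    vpow <- abs(state$x2)^a_exp
    t_b <- (params$b0 + params$b1 * state$x0) * (state$x1 - params$r_damp) *
      c_ss * sign(state$x2) * vpow
  } else {
    fr <- float32_round
    t_sr <- fr(fr(params$k_sr) * fr(L - fr(state$x1 + params$l0_sr)))
    t_pr <- fr(fr(params$k_pr) * fr(state$x1 - params$l0_pr))
    vpow <- if (a_exp == 0.25) {
      quarter_power(abs(fr(state$x2)))
    } else {
      fr(abs(fr(state$x2))^a_exp)
    }
    coef <- fr(params$b0 + fr(params$b1 * state$x0))
    t_b <- fr(fr(fr(coef * fr(state$x1 - params$r_damp)) * fr(c_ss)) *
                fr(sign(state$x2) * vpow))
  }
  list(t_sr = t_sr, t_b = t_b, t_pr = t_pr)
}

#' Time derivatives of one intrafusal fiber
#'
#' `dx1 = x2` and `dx2 = (T_SR - T_B - T_PR - gamma_force * x0) / m`; the
#' reciprocal mass is treated as a precomputed constant (multiplication, not
#' division), as in the combinational hardware datapath.
#'
#' @inheritParams intrafusal_tensions
#' @param input A `spindle_input`.
#' @return Named list with `dx0` (1/s), `dx1` (L0/s), `dx2` (L0/s^2).
#' @export
fiber_derivatives <- function(state, input, params,
                              arith = c("exact", "fpga_faithful"),
                              a_exp = NULL) {
  arith <- match.arg(arith)
  if (params$m <= 0) stop_config("m must be > 0")
  tens <- intrafusal_tensions(state, input$L, params, arith, a_exp)
  dx0 <- fusimotor_activation_derivative(state$x0, .fiber_gamma(params, input),
                                         params)
  inv_m <- 1 / params$m  # precomputed constant
  if (arith == "exact") {
    dx2 <- (tens$t_sr - tens$t_b - tens$t_pr -
              params$gamma_force * state$x0) * inv_m
  } else {
    fr <- float32_round
    net <- fr(fr(fr(tens$t_sr - tens$t_b) - tens$t_pr) -
                fr(fr(params$gamma_force) * fr(state$x0)))
    dx2 <- fr(net * fr(inv_m))
  }
  list(dx0 = dx0, dx1 = state$x2, dx2 = dx2)
}

#' Advance one intrafusal fiber by a fixed time step
#'
#' Integrates the fiber ODEs with fixed explicit substeps (default 10 per
#' 1 ms step, i.e. 0.1 ms internal resolution: the second-order fiber
#' equation with its small mass term is stiff at 1 ms). The position/velocity
#' pair uses the semi-implicit (symplectic) Euler update - velocity first,
#' then position with the new velocity - which is neutrally stable on the
#' stiff spring so the fractional-power damping can bring the fiber to a true
#' rest state; plain forward Euler leaves a small persistent limit cycle.
#' Muscle length and gamma rates are held constant across the step, matching
#' a discrete emulation that latches its inputs once per update. Activation
#' is clipped to `[0, 1]` after each substep.
#'
#' @inheritParams fiber_derivatives
#' @param dt Step length (s), > 0.
#' @param substeps Number of internal Euler substeps (>= 1).
#' @return The advanced `fiber_state`.
#' @export
step_fiber <- function(state, input, params, dt = 0.001,
                       arith = c("exact", "fpga_faithful"),
                       substeps = 10, a_exp = NULL) {
  arith <- match.arg(arith)
  if (dt <= 0) stop_domain("dt must be > 0")
  if (substeps < 1) stop_domain("substeps must be >= 1")
  h <- dt / substeps
  x0 <- state$x0; x1 <- state$x1; x2 <- state$x2
  s <- state
  inv_m <- 1 / params$m
  gamma <- .fiber_gamma(params, input)
  for (i in seq_len(substeps)) {
    tens <- intrafusal_tensions(s, input$L, params, arith, a_exp)
    dx0 <- fusimotor_activation_derivative(x0, gamma, params)
    # split the acceleration so the damping impulse can be capped: within one
    # substep damping may decelerate the polar region at most to rest, never
    # reverse it (the |x2|^a damping law has infinite slope at zero velocity
    # and would otherwise make the velocity chatter around 0)
    x2_free <- x2 + h * (tens$t_sr - tens$t_pr -
                           params$gamma_force * x0) * inv_m
    x0 <- min(1, max(0, x0 + h * dx0))
    dv_damp <- -h * tens$t_b * inv_m
    if (dv_damp * x2_free < 0 && abs(dv_damp) >= abs(x2_free)) {
      x2 <- 0
    } else {
      x2 <- x2_free + dv_damp
    }
    x1 <- x1 + h * x2          # symplectic: position uses the new velocity
    if (!all(is.finite(c(x0, x1, x2)))) {
      stop_numeric("numerical instability integrating fiber ", params$fiber)
    }
    s <- structure(list(x0 = x0, x1 = x1, x2 = x2), class = "fiber_state")
  }
  s
}

#' Spindle configuration
#'
#' Bundles the three fiber parameter sets with the model-level options.
#'
#' @param arithmetic_mode `"exact"` (double precision, velocity exponent 0.3)
#'   or `"fpga_faithful"` (single-precision rounding after each operation,
#'   quarter-power velocity exponent).
#' @param a_exp Velocity exponent override (default: 0.3 exact / 0.25
#'   fpga_faithful); exposed so the exponent and the arithmetic precision can
#'   be ablated independently.
#' @param substeps Euler substeps per 1 ms update.
#' @param occlusion_factor Partial-occlusion weight for the Ia combination:
#'   the larger of the bag1 and bag2+chain primary components contributes
#'   fully, the smaller contributes this fraction. The single most
#'   model-sensitive constant.
#' @param bag1,bag2,chain `fiber_parameters` objects.
#' @return An object of class `spindle_config`.
#' @export
spindle_config <- function(arithmetic_mode = c("exact", "fpga_faithful"),
                           a_exp = NULL, substeps = 10,
                           occlusion_factor = 0.156,
                           bag1 = fiber_parameters("bag1"),
                           bag2 = fiber_parameters("bag2"),
                           chain = fiber_parameters("chain")) {
  arithmetic_mode <- match.arg(arithmetic_mode)
  if (is.null(a_exp)) a_exp <- if (arithmetic_mode == "exact") 0.3 else 0.25
  if (substeps < 1) stop_config("substeps must be >= 1")
  if (occlusion_factor < 0 || occlusion_factor > 1) {
    stop_config("occlusion_factor must lie in [0, 1]")
  }
  structure(list(arithmetic_mode = arithmetic_mode, a_exp = a_exp,
                 substeps = substeps, occlusion_factor = occlusion_factor,
                 fibers = list(bag1 = bag1, bag2 = bag2, chain = chain)),
            class = "spindle_config")
}

#' Whole-spindle state
#'
#' @param bag1,bag2,chain `fiber_state` objects.
#' @export
spindle_state <- function(bag1, bag2, chain) {
  structure(list(bag1 = bag1, bag2 = bag2, chain = chain),
            class = "spindle_state")
}

#' Equilibrium spindle state for constant input
#'
#' Solves the algebraic steady state: activation at its saturating value,
#' zero polar-region velocity, and the polar-region length balancing the
#' sensory spring, polar spring and fusimotor force.
#'
#' @param input A `spindle_input`.
#' @param config A `spindle_config`.
#' @return A `spindle_state`.
#' @export
spindle_equilibrium <- function(input, config = spindle_config()) {
  eq <- lapply(config$fibers, function(p) {
    x0 <- .activation_ss(.fiber_gamma(p, input), p)
    x1 <- (p$k_sr * (input$L - p$l0_sr) + p$k_pr * p$l0_pr -
             p$gamma_force * x0) / (p$k_sr + p$k_pr)
    fiber_state(x0 = x0, x1 = x1, x2 = 0)
  })
  spindle_state(eq$bag1, eq$bag2, eq$chain)
}

# Primary/secondary afferent components of one fiber, from its sensory-region
# tension. Components are expressed in Hz and clipped at zero.
.afferent_components <- function(t_sr, x1, params) {
  sr_stretch <- t_sr / params$k_sr + params$l0_sr  # sensory-region length
  prim <- params$g_primary * max(0, sr_stretch - params$l_n_sr)
  sec <- 0
  if (params$g_secondary > 0) {
    sec <- params$g_secondary *
      (params$x_sec * (params$l_sec / params$l0_sr) *
         max(0, sr_stretch - params$l_n_sr) +
       (1 - params$x_sec) * (params$l_sec / params$l0_pr) *
         max(0, x1 - params$l_n_pr))
  }
  list(primary = prim, secondary = sec)
}

#' Combine per-fiber components into Ia and II firing rates
#'
#' The Ia ending spans all three fibers; their contributions combine with
#' partial occlusion: the larger of the bag1 component and the bag2+chain
#' component contributes fully, the smaller contributes a fraction
#' (`occlusion_factor`). The II ending sums the bag2 and chain secondary
#' components (bag1 has no secondary ending). All rates are clipped at zero.
#'
#' @param bag1_primary,bag2_primary,chain_primary Primary components (Hz).
#' @param bag2_secondary,chain_secondary Secondary components (Hz).
#' @param occlusion_factor Partial-occlusion weight in `[0, 1]`.
#' @return Named list with `ia_rate` and `ii_rate` (Hz).
#' @export
combine_afferents <- function(bag1_primary, bag2_primary, chain_primary,
                              bag2_secondary, chain_secondary,
                              occlusion_factor = 0.156) {
  comp_dyn <- max(0, bag1_primary)
  comp_stat <- max(0, bag2_primary) + max(0, chain_primary)
  ia <- max(comp_dyn, comp_stat) + occlusion_factor * min(comp_dyn, comp_stat)
  ii <- max(0, bag2_secondary) + max(0, chain_secondary)
  list(ia_rate = max(0, ia), ii_rate = max(0, ii))
}

#' Advance the whole spindle by one step
#'
#' Steps all three fibers, then reads out the afferent rates from the updated
#' states. Deterministic for fixed inputs.
#'
#' @param state A `spindle_state`.
#' @param input A `spindle_input`.
#' @param dt Step length (s).
#' @param config A `spindle_config`.
#' @return List with the advanced `state` and `rates` (an `ia_rate`/`ii_rate`
#'   list).
#' @export
step_spindle <- function(state, input, dt = 0.001, config = spindle_config()) {
  arith <- config$arithmetic_mode
  ns <- lapply(names(config$fibers), function(nm) {
    step_fiber(state[[nm]], input, config$fibers[[nm]], dt, arith,
               config$substeps, config$a_exp)
  })
  names(ns) <- names(config$fibers)
  comp <- lapply(names(ns), function(nm) {
    p <- config$fibers[[nm]]
    tens <- intrafusal_tensions(ns[[nm]], input$L, p, arith, config$a_exp)
    .afferent_components(tens$t_sr, ns[[nm]]$x1, p)
  })
  names(comp) <- names(ns)
  rates <- combine_afferents(comp$bag1$primary, comp$bag2$primary,
                             comp$chain$primary, comp$bag2$secondary,
                             comp$chain$secondary, config$occlusion_factor)
  list(state = spindle_state(ns$bag1, ns$bag2, ns$chain), rates = rates)
}

#' Run the spindle model over a waveform
#'
#' Integrates the three-fiber model along a muscle-length waveform on the
#' 1 ms grid and returns the Group Ia and II rate traces. Gamma rates may be
#' scalars (constant drive) or vectors on the same grid (stepped drive).
#' Starts from the equilibrium state for the first sample unless `init_state`
#' is given.
#'
#' @param wave A `spindle_waveform`.
#' @param gamma_dyn,gamma_stat Fusimotor rates (Hz); scalar or per-sample.
#' @param config A `spindle_config`.
#' @param engine `"cpp"` (compiled fast path, default) or `"r"` (reference
#'   implementation built from [step_spindle()]).
#' @param init_state Optional starting `spindle_state`.
#' @return A data.frame with `time_ms`, `ia_rate`, `ii_rate`; the final
#'   `spindle_state` is attached as attribute `final_state`.
#' @export
run_spindle <- function(wave, gamma_dyn = 0, gamma_stat = 0,
                        config = spindle_config(),
                        engine = c("cpp", "r"), init_state = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(wave, "spindle_waveform"))
  n <- length(wave$samples)
  gd <- rep_len(as.numeric(gamma_dyn), n)
  gs <- rep_len(as.numeric(gamma_stat), n)
  if (any(gd < 0) || any(gs < 0)) stop_domain("gamma rates must be >= 0")
  if (is.null(init_state)) {
    init_state <- spindle_equilibrium(
      spindle_input(wave$samples[1], gd[1], gs[1]), config)
  }
  dt <- wave$dt_ms / 1000
  if (engine == "cpp") {
    fp <- lapply(config$fibers, function(p) {
      as.numeric(p[c("k_sr", "k_pr", "m", "l0_sr", "l0_pr", "l_n_sr",
                     "l_n_pr", "r_damp", "c_lengthen", "c_shorten", "p",
                     "omega", "tau", "b0", "b1", "gamma_force", "g_primary",
                     "g_secondary", "x_sec", "l_sec")])
    })
    st <- vapply(init_state[c("bag1", "bag2", "chain")],
                 function(s) c(s$x0, s$x1, s$x2), numeric(3))
    res <- run_spindle_cpp(wave$samples, gd, gs, fp$bag1, fp$bag2, fp$chain,
                           as.numeric(st), dt, as.integer(config$substeps),
                           config$arithmetic_mode == "fpga_faithful",
                           config$a_exp, config$occlusion_factor)
    if (!all(is.finite(res$rates))) {
      stop_numeric("numerical instability in spindle integration")
    }
    out <- data.frame(time_ms = waveform_time(wave),
                      ia_rate = res$rates[, 1], ii_rate = res$rates[, 2])
    fs <- matrix(res$final_state, nrow = 3)
    attr(out, "final_state") <- spindle_state(
      fiber_state(fs[1, 1], fs[2, 1], fs[3, 1]),
      fiber_state(fs[1, 2], fs[2, 2], fs[3, 2]),
      fiber_state(fs[1, 3], fs[2, 3], fs[3, 3]))
    out
  } else {
    ia <- numeric(n); ii <- numeric(n)
    st <- init_state
    for (i in seq_len(n)) {
      stepped <- step_spindle(st,
                              spindle_input(wave$samples[i], gd[i], gs[i]),
                              dt, config)
      st <- stepped$state
      ia[i] <- stepped$rates$ia_rate
      ii[i] <- stepped$rates$ii_rate
    }
    out <- data.frame(time_ms = waveform_time(wave), ia_rate = ia,
                      ii_rate = ii)
    attr(out, "final_state") <- st
    out
  }
}
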