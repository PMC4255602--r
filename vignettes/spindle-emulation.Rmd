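---
title: "Emulating a muscle spindle and its spiking afferents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a muscle spindle and its spiking afferents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlesim)
```

## What this package models

The muscle spindle is the stretch receptor embedded in skeletal muscle. It
reports muscle length and lengthening velocity through two afferent nerve
classes — Group Ia (primary), which carries a strong velocity-dependent
(phasic) component, and Group II (secondary), which mainly follows length
(tonic) — and its sensitivity is re-tuned by two efferent inputs, the gamma
dynamic and gamma static fusimotor drives. `spindlesim` implements the
classic rate-based intrafusal-fiber model of this organ, converts its rate
output into spike trains from populations of noisy Class-1 spiking neurons,
and reproduces the classic stretch protocols used to validate spindle
models. It also provides a "hardware-faithful" arithmetic mode that mirrors
a clock-free single-precision digital datapath, in which division and
fractional powers are built from the fast inverse square root.

## The intrafusal fiber model

Each of the three fibers (bag1, bag2, nuclear chain) is a series
spring–damper sandwich: a stiff *sensory region* (spring constant `k_sr`)
in series with a compliant, contractile *polar region* (spring `k_pr`,
nonlinear damper, mass term `m`). All lengths are normalized to the resting
muscle length L0, so a 36.8 % stretch is `L = 1.368`. The state of a fiber
is

* `x0` — fusimotor activation in [0, 1],
* `x1` — polar-region length (L0),
* `x2` — polar-region velocity (L0/s),

with dynamics

$$\dot x_0 = \left(\frac{\gamma^2}{\gamma^2+\Omega^2} - x_0\right)/\tau,
\qquad \dot x_1 = x_2, \qquad
\dot x_2 = \frac{1}{m}\,(T_{SR} - T_B - T_{PR} - \Gamma_1 x_0),$$

where the tension components are

$$T_{SR} = k_{sr}(L - x_1 - \ell_{0,SR}), \quad
T_{PR} = k_{pr}(x_1 - \ell_{0,PR}), \quad
T_B = (b_0 + b_1 x_0)\,(x_1 - R)\,C\,\mathrm{sign}(x_2)\,|x_2|^{a}.$$

The damping tension `T_B` is the scientifically load-bearing term: its
fractional velocity exponent (`a = 0.3`) produces the spindle's
characteristic high sensitivity to small movements, and its coefficient is
scaled by activation (`b1 > 0` for bag1, so gamma dynamic raises velocity
sensitivity; `b1 < 0` for bag2/chain, where gamma static instead acts
mainly through the contractile bias force `gamma_force * x0`). `C` takes
one of two values by the sign of `x2` (lengthening vs shortening
asymmetry; the tie at `x2 = 0` uses the lengthening value, where `T_B` is
zero anyway). Fusimotor routing is the standard one: gamma dynamic drives
bag1 only, gamma static drives bag2 and chain. The chain fiber has no slow
activation dynamics, so its `tau` is set effectively instantaneous
(1 ms; configurable).

Afferent rates are read out from the sensory-region stretch. Each fiber's
primary component is `g_primary * (T_SR/k_sr + l0_sr - l_n_sr)` clipped at
zero; the Ia rate combines the bag1 component with the bag2+chain component
by *partial occlusion* — the larger contributes fully, the smaller times
`occlusion_factor` (default 0.156). The II rate sums the bag2 and chain
secondary components, each a weighted mixture of sensory-region and
polar-region stretch (bag1 has no secondary ending). Occlusion is the
single most model-sensitive constant: it sets how much the static fibers
add to Ia on top of bag1.

The full parameter tables are the cat-soleus values of the source
intrafusal model, shipped as documented defaults in
`fiber_parameters()` and overridable per fiber through `run_config()`.
Because absolute rates depend on this calibration, every behavioral check
in the package is a qualitative ordering (phasic vs tonic, facilitation by
gamma, burst vs plateau), not an absolute rate.

## Numerical integration

The polar-region equation is stiff: `m` is small (2e-4), so the
spring–mass pair oscillates at ~230 rad/s and a 1 ms step cannot integrate
it explicitly. `step_fiber()` therefore takes fixed substeps (default 10
per 1 ms update, i.e. 0.1 ms) while muscle length and gamma rates stay
latched for the whole 1 ms update, as in a discrete emulator. Two
numerical choices matter:

* **Symplectic update.** Velocity advances first and position uses the new
  velocity. On the near-undamped spring this is neutrally stable, where
  plain forward Euler slowly pumps energy.
* **Capped damping impulse.** `|x2|^0.3` has infinite slope at zero
  velocity, so near rest the damping impulse computed over a finite substep
  overshoots and reverses the velocity, producing a sign-chatter limit
  cycle; through the lengthening/shortening asymmetry that chatter
  rectifies into a spurious ~+3 Hz baseline offset. The integrator instead
  caps the damping impulse so that within one substep damping can stop the
  polar region but never reverse it — which is what a dissipative force
  can do physically. Away from zero velocity the cap is inactive and the
  update is the plain Euler one.

With these choices a spindle held at constant length sits at an exactly
constant baseline rate, and relaxes to its algebraic equilibrium
(`spindle_equilibrium()`) from perturbed starts.

## Hardware-faithful arithmetic

In `arithmetic_mode = "fpga_faithful"` the fiber update mirrors a
combinational single-precision datapath: every multiply/add result is
rounded to float32, reciprocal mass is a precomputed constant (never a
division), and the velocity power uses `a = 0.25` computed as
`Q(Q(x)) = x^{0.25}`, where `Q` is the fast inverse square root
(`fast_inv_sqrt()`): a bit-level magic-constant initial guess plus exactly
one Newton–Raphson refinement. The default magic constant is Lomont's
optimized `0x5f375a86` (the historical `0x5f3759df` is available as an
option); with one refinement the relative error is below 0.2 %, and the
composed division (`approx_divide()`) and quarter power (`quarter_power()`)
stay below 0.5 % across twelve decades. `quarter_power(0)` is defined as 0
by continuity — each `Q` block needs a positive argument, but the damping
term must evaluate at `x2 = 0`. The exponent and the precision are
selectable independently (`a_exp`), so the effect of the 0.3 → 0.25
approximation can be separated from rounding effects. Over the classic
0.368 L0 / 200 ms ramp, the exact and hardware-faithful Ia traces differ
by about 1 % RMS of the trace's dynamic range (the acceptance suite bounds
this at 5 %).

`serialization_budget()` carries the time-multiplexing arithmetic for a
chip whose neurons share one physical circuit: at clock `f_fpga`, with
`c_cycles` clock cycles per neuron update and an update rate of
`accel × f_emu`, at most `floor(f_fpga / (c_cycles × accel × f_emu))`
neurons can be serialized. At 200 MHz, 2 cycles, 1 kHz granularity and
365× real time the bound is 273.97 (≈274).

## From rates to spikes

Each afferent group drives a population (default 128 + 128) of Izhikevich
neurons with the Class-1 parameter set (`a = 0.02`, `b = −0.1`, `c = −55`,
`d = 6`, membrane coefficients 0.04/4.1/108): their firing rate rises
continuously from zero with input current, so a monotone rate→current map
exists. The map is calibrated once (`calibrate_gain()`) by measuring the
noise-free f–I curve and inverting it as a monotone piecewise-linear
interpolant. A straight-line fit is deliberately *not* the default: the
Class-1 f–I curve is concave near threshold, so a line either misses the
working range or places its zero-rate intercept above rheobase. The
zero-rate anchor sits 2 current units below rheobase because the ±2.5 mV
membrane noise is worth about 1.75 units of equivalent current at rest — a
silent spindle must keep its neurons silent even with noise on.

Neuron updates run on the 1 ms grid with the membrane equation split into
two half-steps (the standard stabilization of the quadratic model at this
step size). Membrane noise is uniform, generated per neuron by a 32-bit
maximal-length Galois LFSR (taps 32, 22, 2, 1) seeded by splitting the
master seed, and added to the membrane potential once per step. The "5 mV"
noise amplitude is read as peak-to-peak (samples on ±2.5 mV); the
alternative reading is one config value away (`noise_amplitude_mv`).

Two consequences of the 1 ms grid are worth knowing. First, even without
noise a constant-driven neuron shows a small deterministic inter-spike
dispersion (CV ≈ 0.1) from the interaction of spike phase with the grid;
noise roughly doubles it. Second, because all neurons in a population share
the same drive, their residual count fluctuations are partly common-mode:
adding neurons improves the count–rate correlation only marginally beyond
a few dozen neurons, which is why the white-noise encoding correlation
saturates near 0.8 instead of approaching 1 with 128 neurons.

## Stimuli and experiments

`stimuli` generates every protocol waveform on the 1 ms grid: ramp-and-hold
(the 36.8 % / 200 ms classic, from a 14 mm stretch of a 38 mm rest-length
muscle), sinusoids (0.026 L0 peak-to-peak at 3 Hz), taps, release ramps
with a deliberate velocity discontinuity at the stop, repeated triangles,
and low-pass filtered white noise (second-order Butterworth applied
forward–backward for zero phase, rescaled to a configured span). The tap
shape (raised cosine, 20 ms) and the white-noise span (0.1 L0) are not
fixed by the classic protocols; they are documented defaults. Generators
are pure functions of their arguments plus seed.

The experiment layer reproduces the validation protocols: ramp-and-hold
with fusimotor drive off/on (the "ventral roots cut/intact" contrast; the
tonic level is not standardized, default 50 Hz on both drives), the
sinusoid with a 0→80 Hz gamma step between the 3rd and 4th cycle, the
four-waveform battery (the release run exhibits a transient Ia burst when
the shortening stops abruptly — a sudden stop acts like a momentary
stretch at very high velocity), the repeated-triangle protocol with
trial-averaged instantaneous frequency (initial burst), and the white-noise
encoding-fidelity run (160 s, 5 Hz cutoff, 20 ms count bins; the bin width
is a documented default and the conclusion is robust to 10–50 ms bins).
Correlation p-values use the standard t transform of Pearson r; with
~8000 bins the p < 1e-4 claim is a threshold check.

## What the synthetic stimuli do and do not show

All validation inputs are synthetic waveforms, so passing tests demonstrate
the model's input–output behavior, not fidelity to any particular recorded
kinematics. Real muscle stretch arrives through skin, tendon and tissue
filtering, and real spindles show properties this model deliberately omits:
thixotropy (dependence on stretch history), tendon-organ interactions, and
the full reflex loop. The parameters are cat-calibrated; human spindles
are more chain-dominated and would need re-tuned damping and gains.
Muscle tension is an internal variable of the fiber model, not an exported
observable.

## Problem sizes and determinism

The unit suites run populations of 16 neurons and seconds-long traces; the
acceptance suite runs the full study conditions (128 + 128 neurons, 160 s
white noise, five master seeds, the full protocol battery). Every
simulation is bit-reproducible given (config, seed): waveform seeds,
per-neuron LFSR seeds and experiment seeds all derive from one master seed,
and the stimulus generators restore the global RNG state they borrow.

```{r example, eval = FALSE}
cfg <- run_config()
sah <- stretch_and_hold_experiment(cfg)
sah$cut$stats$ia_dynamic_index    # phasic Ia sensitivity, gamma off
res <- white_noise_correlation(cfg, seed = 1)
c(res$r_ia, res$r_ii)             # encoding fidelity of the populations
```
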