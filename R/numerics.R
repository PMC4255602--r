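#' @useDynLib spindlesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Classed error helpers; the CLI maps these onto exit codes.
stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("spindlesim_domain_error", "error")))
}
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("spindlesim_config_error", "error")))
}
stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("spindlesim_numeric_error", "error")))
}

#' Round doubles to IEEE-754 single precision
#'
#' Passes each value through a 4-byte float, returning the nearest
#' representable single-precision value as a double. Used to mirror a
#' combinational single-precision datapath in which every multiply/add
#' result is rounded before the next operation.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, rounded to float32.
#' @export
float32_round <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}

#' Bit pattern of a single-precision float
#'
#' @param x Numeric vector (converted to float32 first).
#' @return Integer vector holding the 32-bit patterns (as signed R integers).
#' @export
float32_bits <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "integer", n = length(x), size = 4L, endian = "little")
}

#' Reinterpret 32-bit patterns as single-precision floats
#'
#' Inverse of [float32_bits()]: `bits_to_float32(float32_bits(x))` round-trips
#' bit-exactly for all finite float32 values.
#'
#' @param bits Integer vector of 32-bit patterns.
#' @return Numeric vector of the corresponding float values.
#' @export
bits_to_float32 <- function(bits) {
  readBin(writeBin(as.integer(bits), raw(), size = 4L, endian = "little"),
          "double", n = length(bits), size = 4L, endian = "little")
}

# Initial-guess constants for the inverse-square-root bit hack.
MAGIC_LOMONT <- 0x5f375a86L  # Lomont's optimized constant (default)
MAGIC_QUAKE  <- 0x5f3759dfL  # historical Quake III constant, kept as an option

.resolve_magic <- function(magic) {
  if (is.character(magic)) {
    switch(match.arg(magic, c("lomont", "quake")),
           lomont = MAGIC_LOMONT, quake = MAGIC_QUAKE)
  } else {
    as.integer(magic)
  }
}

#' Fast inverse square root (clock-free division primitive)
#'
#' Approximates `1/sqrt(x)` with the magic-constant bit-level initial guess
#' followed by exactly one Newton-Raphson refinement,
#' `y * (1.5 - 0.5 * x * y^2)`. This is the only "division-like" primitive a
#' clock-free combinational datapath needs: ordinary division and the quarter
#' power are both built by composing it (see [approx_divide()],
#' [quarter_power()]). Relative error is below 0.2 percent over many decades.
#'
#' @param x Positive finite numeric vector.
#' @param magic `"lomont"` (default), `"quake"`, or an integer bit constant.
#' @param single If `TRUE` (default) every intermediate operation is rounded
#'   to single precision, mirroring the hardware datapath; if `FALSE` the
#'   refinement runs in double precision (initial guess is bit-level either
#'   way).
#' @return Approximation of `1/sqrt(x)`.
#' @export
fast_inv_sqrt <- function(x, magic = "lomont", single = TRUE) {
  if (length(x) == 0L) return(numeric(0))
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_domain("fast_inv_sqrt requires finite x > 0")
  }
  m <- .resolve_magic(magic)
  xf <- float32_round(x)
  y0 <- bits_to_float32(m - bitwShiftR(float32_bits(xf), 1L))
  if (single) {
    fr <- float32_round
    half_x <- fr(0.5 * xf)
    y2 <- fr(y0 * y0)
    t <- fr(1.5 - fr(half_x * y2))
    fr(y0 * t)
  } else {
    y0 * (1.5 - 0.5 * x * y0 * y0)
  }
}

#' Division via two concatenated inverse-square-root blocks
#'
#' Computes `a / b` as `a * Q(|b|) * Q(|b|)` where `Q` is [fast_inv_sqrt()],
#' with the sign corrected for negative divisors. Sign symmetry is exact:
#' `approx_divide(a, -b)` is bit-identical to `-approx_divide(a, b)`.
#'
#' @param a Numeric vector (dividend).
#' @param b Nonzero finite numeric vector (divisor).
#' @inheritParams fast_inv_sqrt
#' @return Approximation of `a / b` (relative error below 0.5 percent).
#' @export
approx_divide <- function(a, b, magic = "lomont", single = TRUE) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(b == 0)) {
    stop_domain("approx_divide requires finite a, finite nonzero b")
  }
  q <- fast_inv_sqrt(abs(b), magic = magic, single = single)
  if (single) {
    fr <- float32_round
    res <- fr(fr(float32_round(a) * q) * q)
  } else {
    res <- a * q * q
  }
  res * sign(b)
}

#' Quarter power via iterated inverse square root
#'
#' `Q(Q(x)) = (x^-0.5)^-0.5 = x^0.25` for positive `x`. `x = 0` returns 0 by
#' continuity: the exact quarter-power map extends continuously to 0 even
#' though each `Q` block requires a positive argument, and the spindle damping
#' term evaluates `|velocity|^0.25` at rest.
#'
#' @param x Nonnegative finite numeric vector.
#' @inheritParams fast_inv_sqrt
#' @return Approximation of `x^0.25` (relative error below 0.5 percent for
#'   positive `x`).
#' @export
quarter_power <- function(x, magic = "lomont", single = TRUE) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_domain("quarter_power requires finite x >= 0")
  }
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    out[pos] <- fast_inv_sqrt(
      fast_inv_sqrt(x[pos], magic = magic, single = single),
      magic = magic, single = single)
  }
  out
}

#' Time-multiplexing budget for serialized neuron evaluation
#'
#' When emulated neurons time-share one physical arithmetic circuit, the
#' number that can be serialized is limited by the chip clock: updating each
#' of `n` neurons takes `c_cycles` clock cycles, and the whole population must
#' be refreshed `accel * f_emu` times per second. The bound is
#' `n <= f_fpga / (c_cycles * accel * f_emu)`; the largest integer count
#' satisfying it is the floor of that ratio.
#'
#' @param f_fpga Chip clock rate (Hz).
#' @param c_cycles Clock cycles per neuron state update.
#' @param f_emu Emulation granularity rate (Hz), e.g. 1 kHz for 1 ms steps.
#' @param accel Acceleration factor over real time (1 = real time).
#' @return An object of class `serialization_budget`: a list with the inputs,
#'   the real-valued `bound`, and `n_serial_max = floor(bound)`.
#' @examples
#' serialization_budget(200e6, 2, 1000, 365)
#' @export
serialization_budget <- function(f_fpga, c_cycles, f_emu, accel) {
  vals <- c(f_fpga = f_fpga, c_cycles = c_cycles, f_emu = f_emu, accel = accel)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_domain("serialization_budget requires positive finite arguments")
  }
  bound <- f_fpga / (c_cycles * accel * f_emu)
  structure(
    list(f_fpga = f_fpga, c_cycles = c_cycles, f_emu = f_emu, accel = accel,
         bound = bound, n_serial_max = floor(bound)),
    class = "serialization_budget")
}

#' @export
print.serialization_budget <- function(x, ...) {
  cat(sprintf(
    "Serialization budget: %g Hz clock / (%g cycles x %g x %g Hz)\n",
    x$f_fpga, x$c_cycles, x$accel, x$f_emu))
  cat(sprintf("  bound %.2f -> max %d serialized neurons\n",
              x$bound, x$n_serial_max))
  invisible(x)
}
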