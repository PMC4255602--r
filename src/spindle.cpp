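// Compiled inner loops: the three-fiber spindle ODE integration and the
// Izhikevich population with per-neuron LFSR noise. The double-precision
// path is the exact reference arithmetic; the float path reproduces a
// single-precision combinational datapath (every operation rounds to
// float32, velocity power via the fast-inverse-square-root quarter power).

#include <Rcpp.h>
#include <cstring>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---- single-precision primitives -----------------------------------------

static inline float fast_inv_sqrt_f(float x) {
  uint32_t i;
  std::memcpy(&i, &x, 4);
  i = 0x5f375a86u - (i >> 1);
  float y;
  std::memcpy(&y, &i, 4);
  float t = 1.5f - (0.5f * x) * (y * y);
  return y * t;
}

static inline float quarter_power_f(float x) {
  if (x <= 0.0f) return 0.0f;
  return fast_inv_sqrt_f(fast_inv_sqrt_f(x));
}

// ---- fiber model ----------------------------------------------------------

template <typename T>
struct FiberP {
  T k_sr, k_pr, inv_m, l0_sr, l0_pr, l_n_sr, l_n_pr, r_damp, cl, cs,
    p, omega, tau, b0, b1, gforce, gprim, gsec, xsec, lsec;
};

template <typename T>
static FiberP<T> load_fiber(const NumericVector& v) {
  FiberP<T> f;
  f.k_sr = (T)v[0];  f.k_pr = (T)v[1];  f.inv_m = (T)(1.0 / v[2]);
  f.l0_sr = (T)v[3]; f.l0_pr = (T)v[4]; f.l_n_sr = (T)v[5];
  f.l_n_pr = (T)v[6]; f.r_damp = (T)v[7]; f.cl = (T)v[8]; f.cs = (T)v[9];
  f.p = (T)v[10]; f.omega = (T)v[11]; f.tau = (T)v[12];
  f.b0 = (T)v[13]; f.b1 = (T)v[14]; f.gforce = (T)v[15];
  f.gprim = (T)v[16]; f.gsec = (T)v[17]; f.xsec = (T)v[18]; f.lsec = (T)v[19];
  return f;
}

template <typename T>
static inline T vel_power(T x2, T a_exp, bool fpga) {
  T ax = std::abs(x2);
  if (fpga && a_exp == (T)0.25) return (T)quarter_power_f((float)ax);
  if (ax == (T)0) return (T)0;
  return std::pow(ax, a_exp);
}

// One semi-implicit (symplectic) Euler substep; inputs held constant across
// the step. Velocity updates first, position uses the new velocity.
template <typename T>
static inline void fiber_substep(T& x0, T& x1, T& x2, T L, T gamma,
                                 const FiberP<T>& f, T h, T a_exp,
                                 bool fpga) {
  T gp = gamma * gamma;           // saturation exponent p = 2
  T ss = (gp == (T)0) ? (T)0 : gp / (gp + f.omega * f.omega);
  T dx0 = (ss - x0) / f.tau;
  T t_sr = f.k_sr * (L - x1 - f.l0_sr);
  T t_pr = f.k_pr * (x1 - f.l0_pr);
  T c_ss = (x2 < (T)0) ? f.cs : f.cl;
  T sgn = (x2 > (T)0) ? (T)1 : ((x2 < (T)0) ? (T)-1 : (T)0);
  T t_b = (f.b0 + f.b1 * x0) * (x1 - f.r_damp) * c_ss * sgn *
          vel_power(x2, a_exp, fpga);
  // damping impulse is capped: it can stop the polar region within a substep
  // but never reverse it (regularizes the fractional-power damping at 0)
  T x2_free = x2 + h * (t_sr - t_pr - f.gforce * x0) * f.inv_m;
  x0 += h * dx0;
  if (x0 < (T)0) x0 = (T)0;
  if (x0 > (T)1) x0 = (T)1;
  T dv_damp = -h * t_b * f.inv_m;
  if (dv_damp * x2_free < (T)0 && std::abs(dv_damp) >= std::abs(x2_free)) {
    x2 = (T)0;
  } else {
    x2 = x2_free + dv_damp;
  }
  x1 += h * x2;
}

template <typename T>
static inline void afferent_components(T x1, T L, const FiberP<T>& f,
                                       double& prim, double& sec) {
  double t_sr = (double)f.k_sr * ((double)L - (double)x1 - (double)f.l0_sr);
  double sr_stretch = t_sr / (double)f.k_sr + (double)f.l0_sr;
  double supra = sr_stretch - (double)f.l_n_sr;
  prim = (double)f.gprim * (supra > 0 ? supra : 0);
  sec = 0.0;
  if (f.gsec > (T)0) {
    double polar = (double)x1 - (double)f.l_n_pr;
    sec = (double)f.gsec *
          ((double)f.xsec * ((double)f.lsec / (double)f.l0_sr) *
               (supra > 0 ? supra : 0) +
           (1.0 - (double)f.xsec) * ((double)f.lsec / (double)f.l0_pr) *
               (polar > 0 ? polar : 0));
  }
}

template <typename T>
static List run_spindle_impl(const NumericVector& L, const NumericVector& gd,
                             const NumericVector& gs, const NumericVector& p1,
                             const NumericVector& p2, const NumericVector& p3,
                             const NumericVector& init, double dt,
                             int substeps, bool fpga, double a_exp,
                             double occl) {
  const int n = L.size();
  FiberP<T> f[3] = {load_fiber<T>(p1), load_fiber<T>(p2), load_fiber<T>(p3)};
  T x0[3], x1[3], x2[3];
  for (int k = 0; k < 3; ++k) {
    x0[k] = (T)init[3 * k];
    x1[k] = (T)init[3 * k + 1];
    x2[k] = (T)init[3 * k + 2];
  }
  T h = (T)(dt / substeps);
  T ae = (T)a_exp;
  NumericMatrix rates(n, 2);
  for (int i = 0; i < n; ++i) {
    T Li = (T)L[i];
    T gam[3] = {(T)gd[i], (T)gs[i], (T)gs[i]};  // bag1 | bag2 | chain routing
    for (int s = 0; s < substeps; ++s) {
      for (int k = 0; k < 3; ++k) {
        fiber_substep(x0[k], x1[k], x2[k], Li, gam[k], f[k], h, ae, fpga);
      }
    }
    double prim[3], sec[3];
    for (int k = 0; k < 3; ++k) {
      afferent_components(x1[k], Li, f[k], prim[k], sec[k]);
    }
    double comp_dyn = prim[0];
    double comp_stat = prim[1] + prim[2];
    double hi = comp_dyn > comp_stat ? comp_dyn : comp_stat;
    double lo = comp_dyn > comp_stat ? comp_stat : comp_dyn;
    double ia = hi + occl * lo;
    double ii = sec[1] + sec[2];
    rates(i, 0) = ia > 0 ? ia : 0;
    rates(i, 1) = ii > 0 ? ii : 0;
  }
  NumericVector final_state(9);
  for (int k = 0; k < 3; ++k) {
    final_state[3 * k] = (double)x0[k];
    final_state[3 * k + 1] = (double)x1[k];
    final_state[3 * k + 2] = (double)x2[k];
  }
  return List::create(_["rates"] = rates, _["final_state"] = final_state);
}

// [[Rcpp::export]]
List run_spindle_cpp(NumericVector L, NumericVector gd, NumericVector gs,
                     NumericVector p1, NumericVector p2, NumericVector p3,
                     NumericVector init, double dt, int substeps, bool fpga,
                     double a_exp, double occl) {
  if (fpga) {
    return run_spindle_impl<float>(L, gd, gs, p1, p2, p3, init, dt, substeps,
                                   true, a_exp, occl);
  }
  return run_spindle_impl<double>(L, gd, gs, p1, p2, p3, init, dt, substeps,
                                  false, a_exp, occl);
}

// ---- LFSR noise ------------------------------------------------------------

// 32-bit maximal-length Galois LFSR (taps 32, 22, 2, 1).
static inline uint32_t lfsr_step(uint32_t s) {
  uint32_t lsb = s & 1u;
  s >>= 1;
  if (lsb) s ^= 0x80200003u;
  return s;
}

// [[Rcpp::export]]
List lfsr_sequence_cpp(int seed, int n, double amplitude) {
  uint32_t s = (uint32_t)seed;
  if (s == 0u) stop("LFSR seed must be nonzero");
  NumericVector out(n);
  const double inv = 1.0 / 4294967296.0;
  for (int i = 0; i < n; ++i) {
    s = lfsr_step(s);
    out[i] = ((double)s * inv - 0.5) * amplitude;
  }
  return List::create(_["samples"] = out, _["state"] = (double)s);
}

// ---- Izhikevich population -------------------------------------------------

// One 1 ms update: uniform LFSR noise added to v, then two half-steps of the
// quadratic membrane equation, one full step of the recovery variable, and
// the peak/reset rule. Matches the R-level izhikevich_step().
// [[Rcpp::export]]
List run_izh_population_cpp(NumericVector epsc, int n_neurons,
                            IntegerVector seeds, double noise_amp,
                            NumericVector pars, double v0, double u0) {
  const int nt = epsc.size();
  const double a = pars[0], b = pars[1], c = pars[2], d = pars[3];
  const double k2 = pars[4], k1 = pars[5], k0 = pars[6], vpeak = pars[7];
  std::vector<double> v(n_neurons, v0), u(n_neurons, u0);
  std::vector<uint32_t> st(n_neurons);
  for (int j = 0; j < n_neurons; ++j) {
    uint32_t s = (uint32_t)seeds[j];
    if (s == 0u) stop("LFSR seed must be nonzero");
    st[j] = s;
  }
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  const double inv = 1.0 / 4294967296.0;
  for (int t = 0; t < nt; ++t) {
    const double I = epsc[t];
    for (int j = 0; j < n_neurons; ++j) {
      double vj = v[j], uj = u[j];
      if (noise_amp > 0) {
        st[j] = lfsr_step(st[j]);
        vj += ((double)st[j] * inv - 0.5) * noise_amp;
      }
      vj += 0.5 * (k2 * vj * vj + k1 * vj + k0 - uj + I);
      vj += 0.5 * (k2 * vj * vj + k1 * vj + k0 - uj + I);
      uj += a * (b * vj - uj);
      if (vj >= vpeak) {
        spike_t.push_back((double)t);
        spike_id.push_back(j);
        vj = c;
        uj += d;
      }
      if (!std::isfinite(vj) || !std::isfinite(uj)) {
        stop("non-finite neuron state at step %d", t);
      }
      v[j] = vj;
      u[j] = uj;
    }
  }
  return List::create(_["time_ms"] = wrap(spike_t),
                      _["neuron_id"] = wrap(spike_id),
                      _["v"] = wrap(v), _["u"] = wrap(u));
}
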