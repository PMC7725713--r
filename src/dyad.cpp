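#include <Rcpp.h>
using namespace Rcpp;

// Hybrid Rayleigh--van der Pol oscillator with HKB-type coupling.
//
// Each effector obeys
//   xdd + (alpha x^2 + beta xd^2 - gamma) xd + omega^2 x = C
// with coupling to the partner's (held or live) state
//   C = -(xd - mu xd_o) * (a - b (x - mu x_o)^2)
// mu in {+1, -1} encodes the intended coordination pattern (in-/anti-phase).
// With the oscillator calibrated to a limit-cycle amplitude of 2 units this
// coupling reduces, by rotating-wave averaging, to the HKB phase equation
// phi_dot = dOmega - a_red sin(phi) - 2 b_red sin(2 phi).

struct Osc {
  double alpha, beta, gamma, omega2;
};
struct Cpl {
  double a, b, mu;
};

static inline double accel(double x, double v, double xo, double vo,
                           const Osc &o, const Cpl &c) {
  double dv = v - c.mu * vo;
  double dx = x - c.mu * xo;
  double force = -dv * (c.a - c.b * dx * dx);
  return -(o.alpha * x * x + o.beta * v * v - o.gamma) * v - o.omega2 * x + force;
}

// One RK4 step of the full bidirectional 4-dim system.
static inline void rk4_step(double *s, const Osc &o1, const Cpl &c1,
                            const Osc &o2, const Cpl &c2, double dt) {
  double k[4][4], tmp[4];
  const double w[4] = {0.0, 0.5, 0.5, 1.0};
  for (int j = 0; j < 4; ++j) {
    for (int i = 0; i < 4; ++i)
      tmp[i] = s[i] + (j == 0 ? 0.0 : w[j] * dt * k[j - 1][i]);
    k[j][0] = tmp[1];
    k[j][1] = accel(tmp[0], tmp[1], tmp[2], tmp[3], o1, c1);
    k[j][2] = tmp[3];
    k[j][3] = accel(tmp[2], tmp[3], tmp[0], tmp[1], o2, c2);
  }
  for (int i = 0; i < 4; ++i)
    s[i] += dt / 6.0 * (k[0][i] + 2.0 * k[1][i] + 2.0 * k[2][i] + k[3][i]);
}

// [[Rcpp::export]]
List dyad_integrate_cpp(int n_steps, double dt, NumericVector state0,
                        NumericVector osc1, NumericVector cpl1,
                        NumericVector osc2, NumericVector cpl2,
                        double noise_sd) {
  Osc o1{osc1[0], osc1[1], osc1[2], osc1[3] * osc1[3]};
  Osc o2{osc2[0], osc2[1], osc2[2], osc2[3] * osc2[3]};
  Cpl c1{cpl1[0], cpl1[1], cpl1[2]};
  Cpl c2{cpl2[0], cpl2[1], cpl2[2]};

  NumericVector x1(n_steps + 1), v1(n_steps + 1), x2(n_steps + 1), v2(n_steps + 1);
  double s[4] = {state0[0], state0[1], state0[2], state0[3]};
  x1[0] = s[0]; v1[0] = s[1]; x2[0] = s[2]; v2[0] = s[3];

  int diverged_at = 0;
  double sq_dt = std::sqrt(dt);
  for (int i = 1; i <= n_steps; ++i) {
    rk4_step(s, o1, c1, o2, c2, dt);
    if (noise_sd > 0.0) s[1] += noise_sd * sq_dt * R::norm_rand();
    bool ok = true;
    for (int j = 0; j < 4; ++j)
      if (!std::isfinite(s[j]) || std::fabs(s[j]) > 1e6) ok = false;
    if (!ok) { diverged_at = i; break; }
    x1[i] = s[0]; v1[i] = s[1]; x2[i] = s[2]; v2[i] = s[3];
  }
  return List::create(_["x1"] = x1, _["v1"] = v1, _["x2"] = x2, _["v2"] = v2,
                      _["diverged_at"] = diverged_at);
}

static double median_of(std::vector<double> v) {
  if (v.empty()) return 0.0;
  size_t k = v.size() / 2;
  std::nth_element(v.begin(), v.begin() + k, v.end());
  double m = v[k];
  if (v.size() % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + k - 1, v.end());
    m = 0.5 * (m + v[k - 1]);
  }
  return m;
}

// Median per-cycle peak-to-peak amplitude of x[from..n); cycles delimited by
// upward mean-crossings.
static double median_cycle_amp(const double *x, int from, int n) {
  double mean = 0.0;
  for (int i = from; i < n; ++i) mean += x[i];
  mean /= (n - from);
  std::vector<double> amps;
  int prev_up = -1;
  for (int i = from + 1; i < n; ++i) {
    if (x[i - 1] - mean < 0.0 && x[i] - mean >= 0.0) {
      if (prev_up >= 0) {
        double lo = x[prev_up], hi = x[prev_up];
        for (int j = prev_up; j < i; ++j) {
          if (x[j] < lo) lo = x[j];
          if (x[j] > hi) hi = x[j];
        }
        amps.push_back(hi - lo);
      }
      prev_up = i;
    }
  }
  return median_of(amps);
}

// Whole-session integration: every trial of a protocol in one call.
// Returns per-trial summary statistics (median cycle amplitudes of both
// channels on the post-cutoff segment, state-phase mean resultant length)
// and, optionally, the raw traces. Noise uses R's RNG.
// [[Rcpp::export]]
List session_integrate_cpp(int n_trials, int n_steps, double dt, int cut_idx,
                           NumericVector osc_h, NumericVector osc_v,
                           double a_h, double a_v, double b,
                           NumericVector mu_h, NumericVector mu_v,
                           NumericVector init_offsets, double noise_sd,
                           bool keep_traces) {
  Osc o1{osc_h[0], osc_h[1], osc_h[2], osc_h[3] * osc_h[3]};
  Osc o2{osc_v[0], osc_v[1], osc_v[2], osc_v[3] * osc_v[3]};
  double denom1 = o1.alpha + 3.0 * o1.beta * o1.omega2;
  double denom2 = o2.alpha + 3.0 * o2.beta * o2.omega2;
  double r1 = denom1 > 0 ? std::sqrt(4.0 * o1.gamma / denom1) : 2.0;
  double r2 = denom2 > 0 ? std::sqrt(4.0 * o2.gamma / denom2) : 2.0;
  double om1 = std::sqrt(o1.omega2), om2 = std::sqrt(o2.omega2);

  NumericVector amp_h(n_trials), amp_v(n_trials), mrl(n_trials);
  IntegerVector diverged(n_trials);
  List traces(keep_traces ? n_trials : 0);
  double sq_dt = std::sqrt(dt);
  int m = n_steps + 1;
  std::vector<double> x1(m), v1(m), x2(m), v2(m);

  for (int tr = 0; tr < n_trials; ++tr) {
    Cpl c1{a_h, b, mu_h[tr]};
    Cpl c2{a_v, b, mu_v[tr]};
    double s[4] = {r1, 0.0,
                   r2 * std::cos(init_offsets[tr]),
                   -om2 * r2 * std::sin(init_offsets[tr])};
    x1[0] = s[0]; v1[0] = s[1]; x2[0] = s[2]; v2[0] = s[3];
    int div = 0;
    for (int i = 1; i <= n_steps; ++i) {
      rk4_step(s, o1, c1, o2, c2, dt);
      if (noise_sd > 0.0) s[1] += noise_sd * sq_dt * R::norm_rand();
      bool ok = true;
      for (int j = 0; j < 4; ++j)
        if (!std::isfinite(s[j]) || std::fabs(s[j]) > 1e6) ok = false;
      if (!ok) { div = i; break; }
      x1[i] = s[0]; v1[i] = s[1]; x2[i] = s[2]; v2[i] = s[3];
    }
    diverged[tr] = div;
    if (div > 0) continue;
    amp_h[tr] = median_cycle_amp(x1.data(), cut_idx, m);
    amp_v[tr] = median_cycle_amp(x2.data(), cut_idx, m);
    // state-phase relative phase MRL on the post-cutoff segment
    double cs = 0.0, sn = 0.0;
    for (int i = cut_idx; i < m; ++i) {
      double ph = std::atan2(-v1[i] / om1, x1[i]) -
                  std::atan2(-v2[i] / om2, x2[i]);
      cs += std::cos(ph);
      sn += std::sin(ph);
    }
    mrl[tr] = std::sqrt(cs * cs + sn * sn) / (m - cut_idx);
    if (keep_traces) {
      NumericMatrix M(m, 2);
      for (int i = 0; i < m; ++i) { M(i, 0) = x1[i]; M(i, 1) = x2[i]; }
      traces[tr] = M;
    }
  }
  return List::create(_["amp_h"] = amp_h, _["amp_v"] = amp_v, _["mrl"] = mrl,
                      _["diverged"] = diverged, _["traces"] = traces);
}

// Per-cycle peak-to-peak amplitudes, cycles delimited by upward
// mean-crossings of the (already mean-centered) series.
// [[Rcpp::export]]
NumericVector cycle_amplitudes_cpp(NumericVector x) {
  int n = x.size();
  std::vector<int> up;
  for (int i = 1; i < n; ++i)
    if (x[i - 1] < 0.0 && x[i] >= 0.0) up.push_back(i);
  std::vector<double> amps;
  for (size_t c = 1; c < up.size(); ++c) {
    double lo = x[up[c - 1]], hi = x[up[c - 1]];
    for (int i = up[c - 1]; i < up[c]; ++i) {
      if (x[i] < lo) lo = x[i];
      if (x[i] > hi) hi = x[i];
    }
    amps.push_back(hi - lo);
  }
  return wrap(amps);
}
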