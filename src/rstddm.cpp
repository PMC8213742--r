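#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parameter vector layout used throughout:
// [0] noise, [1] sp_bias, [2] ndt, [3] rst, [4] w_taste, [5] w_health, [6] drift_bias
// Bounds are fixed at [-1, +1]; the accumulator starts at x0 = 2*sp_bias - 1.

static inline void onsets(double rst, double &on_taste, double &on_health) {
  // rst = onset(health) - onset(taste); the earlier attribute starts at 0.
  if (rst >= 0.0) { on_taste = 0.0; on_health = rst; }
  else            { on_health = 0.0; on_taste = -rst; }
}

static inline double drift_value(const double *par, double td, double hd, double t) {
  double on_t, on_h;
  onsets(par[3], on_t, on_h);
  double v = par[6];
  if (t >= on_t) v += par[4] * td;
  if (t >= on_h) v += par[5] * hd;
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_drift_at(NumericVector par, double td, double hd, NumericVector t) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = drift_value(REAL(par), td, hd, t[i]);
  return out;
}

// Simulate one trial; piecewise-constant drift so each Euler step is an exact
// Gaussian transition. Within-step boundary crossings are detected with the
// Brownian-bridge crossing probability, removing first-order discretisation
// bias in choice probabilities. Returns decision time (no NDT added), choice
// (+1 upper / -1 lower), or 0 if still diffusing at t_max.
static int sim_one(const double *par, double td, double hd, double dt,
                   double t_max, double &t_dec) {
  const double sigma = par[0];
  const double sig2dt_inv_base = 1.0; // placeholder, recomputed per step
  (void)sig2dt_inv_base;
  double on_t, on_h;
  onsets(par[3], on_t, on_h);
  double x = 2.0 * par[1] - 1.0;
  double t = 0.0;
  // immediate absorption if start on/outside a bound (sp_bias at extremes)
  if (x >= 1.0)  { t_dec = 0.0; return +1; }
  if (x <= -1.0) { t_dec = 0.0; return -1; }
  while (t < t_max) {
    // step up to next drift-onset boundary so drift is constant within step
    double h = dt;
    if (t < on_t && t + h > on_t) h = on_t - t;
    if (t < on_h && t + h > on_h) h = on_h - t;
    if (t + h > t_max) h = t_max - t;
    if (h <= 0.0) { t += 1e-12; continue; }
    double v = drift_value(par, td, hd, t);
    double xn = x + v * h + sigma * std::sqrt(h) * norm_rand();
    if (xn >= 1.0)  { t_dec = t + h; return +1; }
    if (xn <= -1.0) { t_dec = t + h; return -1; }
    // bridge crossing probabilities for each bound
    double s2h = sigma * sigma * h;
    double p_up  = std::exp(-2.0 * (1.0 - x) * (1.0 - xn) / s2h);
    double p_low = std::exp(-2.0 * (1.0 + x) * (1.0 + xn) / s2h);
    if (unif_rand() < p_up)  { t_dec = t + 0.5 * h; return +1; }
    if (unif_rand() < p_low) { t_dec = t + 0.5 * h; return -1; }
    x = xn;
    t += h;
  }
  t_dec = t_max;
  return 0;
}

// [[Rcpp::export]]
List cpp_simulate_trials(NumericVector par, NumericVector td, NumericVector hd,
                         double dt, double deadline) {
  int n = td.size();
  IntegerVector chose_left(n);
  NumericVector rt(n);
  IntegerVector censored(n);
  const double *p = REAL(par);
  double t_budget = deadline - p[2]; // decision-time budget after NDT
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double t_dec;
    int side = 0;
    if (t_budget > 0.0) side = sim_one(p, td[i], hd[i], dt, t_budget, t_dec);
    if (side == 0) {
      chose_left[i] = NA_INTEGER; rt[i] = NA_REAL; censored[i] = 1;
    } else {
      chose_left[i] = (side > 0) ? 1 : 0;
      rt[i] = t_dec + p[2];
      censored[i] = 0;
    }
  }
  return List::create(_["chose_left"] = chose_left, _["rt"] = rt,
                      _["censored"] = censored);
}

// ---------------------------------------------------------------------------
// Fokker-Planck solver: Crank-Nicolson (Rannacher-started) finite differences
// on [-1, 1] with absorbing bounds; drift piecewise constant in time (one
// switch at the later attribute onset). Boundary absorption per step is
// allocated from the exact per-step mass balance, split in proportion to the
// one-sided diffusive boundary fluxes, so total mass is conserved to solver
// round-off by construction.
// ---------------------------------------------------------------------------

struct FPTSolver {
  int M;              // number of intervals; nodes 0..M, interior 1..M-1
  double dx, D;
  std::vector<double> p;        // interior densities, length M-1
  std::vector<double> a, b, c, r, gam; // tridiagonal workspaces

  FPTSolver(int M_, double dx_, double sigma) : M(M_), dx(dx_),
      D(0.5 * sigma * sigma), p(M_ - 1, 0.0),
      a(M_ - 1), b(M_ - 1), c(M_ - 1), r(M_ - 1), gam(M_ - 1) {}

  void init_delta(double x0) {
    // split unit mass between the two nodes bracketing x0 (mean-preserving)
    std::fill(p.begin(), p.end(), 0.0);
    double pos = (x0 + 1.0) / dx;        // node index as real
    int i = (int)std::floor(pos);
    double w = pos - i;
    // interior indices are 1..M-1 -> vector offset i-1
    if (i >= 1 && i <= M - 1) p[i - 1] += (1.0 - w) / dx;
    if (i + 1 >= 1 && i + 1 <= M - 1) p[i] += w / dx;
  }

  double mass() const {
    double s = 0.0;
    for (double v : p) s += v;
    return s * dx; // trapezoid with zero boundary values
  }

  // one theta-scheme step of size h with constant drift v
  void step(double h, double v, double theta) {
    int n = M - 1;
    double adv = v / (2.0 * dx), dif = D / (dx * dx);
    // L p (row i): (dif + adv) p_{i-1} - 2 dif p_i + (dif - adv) p_{i+1}
    double lo = dif + adv, di = -2.0 * dif, up = dif - adv;
    // rhs = (I + (1-theta) h L) p
    for (int i = 0; i < n; ++i) {
      double s = (1.0 + (1.0 - theta) * h * di) * p[i];
      if (i > 0)     s += (1.0 - theta) * h * lo * p[i - 1];
      if (i < n - 1) s += (1.0 - theta) * h * up * p[i + 1];
      r[i] = s;
      a[i] = -theta * h * lo;
      b[i] = 1.0 - theta * h * di;
      c[i] = -theta * h * up;
    }
    // Thomas algorithm
    double bet = b[0];
    p[0] = r[0] / bet;
    for (int i = 1; i < n; ++i) {
      gam[i] = c[i - 1] / bet;
      bet = b[i] - a[i] * gam[i];
      p[i] = (r[i] - a[i] * p[i - 1]) / bet;
    }
    for (int i = n - 2; i >= 0; --i) p[i] -= gam[i + 1] * p[i + 1];
    for (int i = 0; i < n; ++i) if (p[i] < 0.0) p[i] = 0.0;
  }

  // one-sided second-order diffusive boundary fluxes (outgoing)
  double flux_up() const {
    int n = M - 1;
    double d1 = (4.0 * p[n - 1] - (n >= 2 ? p[n - 2] : 0.0)) / (2.0 * dx);
    return D * d1;
  }
  double flux_low() const {
    double d1 = (4.0 * p[0] - (M - 1 >= 2 ? p[1] : 0.0)) / (2.0 * dx);
    return D * d1;
  }
};

// Advance solver through [t, t+dt] honouring the drift switch at ts.
static void advance_step(FPTSolver &S, double t, double dt, double v1, double v2,
                         double ts, double theta) {
  double t_end = t + dt;
  if (ts > t && ts < t_end) {
    S.step(ts - t, v1, theta);
    S.step(t_end - ts, v2, theta);
  } else {
    double v = (t >= ts) ? v2 : v1;
    S.step(dt, v, theta);
  }
}

// Core FPT run: returns boundary densities g_up/g_low at times k*dt, k=1..n_steps,
// and survival mass after each step.
static void fpt_run(const double *par, double td, double hd, double t_max,
                    double dt, double dx, std::vector<double> &g_up,
                    std::vector<double> &g_low, std::vector<double> &surv) {
  double on_t, on_h;
  onsets(par[3], on_t, on_h);
  double ts = std::max(on_t, on_h);       // single switch time (earlier is 0)
  double v_early = drift_value(par, td, hd, 0.0);
  double v_late  = drift_value(par, td, hd, ts);
  int M = std::max(8, (int)std::round(2.0 / dx));
  FPTSolver S(M, 2.0 / M, par[0]);
  S.init_delta(2.0 * par[1] - 1.0);
  int n_steps = (int)std::ceil(t_max / dt - 1e-9);
  g_up.assign(n_steps, 0.0);
  g_low.assign(n_steps, 0.0);
  surv.assign(n_steps, 0.0);
  double m_prev = S.mass();
  const int n_rannacher = 4;
  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    double theta = (k < n_rannacher) ? 1.0 : 0.5;
    // restart with backward Euler around the drift switch: the solution has a
    // kink there and Crank-Nicolson would otherwise ring
    if (ts > 0.0 && t + dt > ts && t < ts + n_rannacher * dt) theta = 1.0;
    advance_step(S, t, dt, v_early, v_late, ts, theta);
    double m_now = S.mass();
    double dM = m_prev - m_now;
    if (dM < 0.0) dM = 0.0;
    double fu = S.flux_up(), fl = S.flux_low();
    if (fu < 0.0) fu = 0.0;
    if (fl < 0.0) fl = 0.0;
    double tot = fu + fl;
    double wu = (tot > 0.0) ? fu / tot : 0.5;
    g_up[k]  = dM / dt * wu;
    g_low[k] = dM / dt * (1.0 - wu);
    surv[k] = m_now;
    m_prev = m_now;
  }
}

// [[Rcpp::export]]
List cpp_fpt_solve(NumericVector par, double td, double hd, double t_max,
                   double dt, double dx) {
  std::vector<double> g_up, g_low, surv;
  fpt_run(REAL(par), td, hd, t_max, dt, dx, g_up, g_low, surv);
  int n = g_up.size();
  NumericVector t(n), gu(n), gl(n), sv(n);
  for (int k = 0; k < n; ++k) {
    t[k] = (k + 1) * dt;
    gu[k] = g_up[k]; gl[k] = g_low[k]; sv[k] = surv[k];
  }
  return List::create(_["t"] = t, _["upper"] = gu, _["lower"] = gl,
                      _["survival"] = sv);
}

// linear interpolation of the step-wise boundary density at decision time t
static double interp_g(const std::vector<double> &g, double dt, double t) {
  int n = g.size();
  if (t <= 0.0 || n == 0) return 0.0;
  double pos = t / dt; // density index k corresponds to time (k+1)*dt
  int k1 = (int)std::floor(pos);         // bracketing: k1*dt <= t < (k1+1)*dt
  double w = pos - k1;
  double g0 = (k1 >= 1) ? g[std::min(k1 - 1, n - 1)] : 0.0;
  double g1 = g[std::min(k1, n - 1)];
  return (1.0 - w) * g0 + w * g1;
}

// [[Rcpp::export]]
double cpp_loglik(NumericVector par, NumericVector td, NumericVector hd,
                  IntegerVector chose_left, NumericVector rt,
                  double deadline, double dt, double dx, double eps,
                  bool truncate) {
  const double *p = REAL(par);
  double ndt = p[2];
  double ll = 0.0;
  int n = td.size();
  std::vector<double> g_up, g_low, surv;
  for (int i = 0; i < n; ++i) {
    double t_dec = rt[i] - ndt;
    if (t_dec <= 0.0) return R_NegInf; // guarded on the R side with a message
    double t_solve = truncate ? std::max(t_dec, deadline - ndt) : t_dec;
    fpt_run(p, td[i], hd[i], t_solve, dt, dx, g_up, g_low, surv);
    double g = chose_left[i] == 1 ? interp_g(g_up, dt, t_dec)
                                  : interp_g(g_low, dt, t_dec);
    if (g < eps) g = eps;
    ll += std::log(g);
    if (truncate) {
      double absorbed = 1.0 - surv.back();
      if (absorbed < eps) absorbed = eps;
      ll -= std::log(absorbed);
    }
  }
  return ll;
}
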