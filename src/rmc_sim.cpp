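#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout (fixed everywhere):
// p[0]=mu1 p[1]=mu2 p[2]=p1 p[3]=p2 p[4]=p3 p[5]=p4 p[6]=p5
// p[7]=alpha p[8]=beta p[9]=r

static inline void rhs(const double* x, const double* p, double* dx) {
  const double B = x[0], E = x[1], Ti = x[2], Tu = x[3];
  dx[0] = -p[0] * B - p[2] * E * B - p[3] * B * Tu;
  dx[1] = -p[1] * E + p[7] * Ti + p[5] * E * B - p[6] * E * Ti;
  dx[2] = -p[4] * E * Ti + p[3] * B * Tu;
  dx[3] = -p[3] * B * Tu + p[9] * (1.0 - p[8] * Tu) * Tu;
}

// one classical RK4 step in place; returns false on non-finite state
static inline bool rk4(double* x, const double* p, double dt) {
  double k1[4], k2[4], k3[4], k4[4], xt[4];
  rhs(x, p, k1);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
  rhs(xt, p, k2);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
  rhs(xt, p, k3);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + dt * k3[i];
  rhs(xt, p, k4);
  bool ok = true;
  for (int i = 0; i < 4; ++i) {
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (!std::isfinite(x[i])) ok = false;
  }
  return ok;
}

// Full trajectory. imp_idx: 0-based grid indices (sorted, may repeat),
// impulse applied at the START of step k; stored row k is post-impulse.
// [[Rcpp::export]]
NumericMatrix sim_path_cpp(NumericVector par, NumericVector x0,
                           IntegerVector imp_idx, NumericVector imp_dose,
                           int kt, double dt) {
  NumericMatrix out(kt + 1, 4);
  double x[4];
  const double* p = REAL(par);
  for (int i = 0; i < 4; ++i) x[i] = x0[i];
  R_xlen_t ni = imp_idx.size(), j = 0;
  for (int k = 0; k <= kt; ++k) {
    while (j < ni && imp_idx[j] == k) { x[0] += imp_dose[j]; ++j; }
    for (int i = 0; i < 4; ++i) out(k, i) = x[i];
    if (k < kt) {
      if (!rk4(x, p, dt))
        stop("integration blow-up at step %d (t = %.2f days)", k + 1,
             (k + 1) * dt);
    }
  }
  return out;
}

// Summary quantities of one run without storing the path.
// Returns [stage_sum = sum_k Tu(k)*dt (k = 0..kt), tu_final, tu_max,
//          settle_time (NA if never below frac*Tu(0))].
// [[Rcpp::export]]
NumericVector sim_metrics_cpp(NumericVector par, NumericVector x0,
                              IntegerVector imp_idx, NumericVector imp_dose,
                              int kt, double dt, double frac) {
  double x[4];
  const double* p = REAL(par);
  for (int i = 0; i < 4; ++i) x[i] = x0[i];
  R_xlen_t ni = imp_idx.size(), j = 0;
  double stage = 0.0, tumax = 0.0, settle = NA_REAL;
  const double thr = frac * x0[3];
  for (int k = 0; k <= kt; ++k) {
    while (j < ni && imp_idx[j] == k) { x[0] += imp_dose[j]; ++j; }
    stage += x[3] * dt;
    if (x[3] > tumax) tumax = x[3];
    if (ISNA(settle) && x[3] < thr) settle = k * dt;
    if (k < kt) {
      if (!rk4(x, p, dt))
        stop("integration blow-up at step %d (t = %.2f days)", k + 1,
             (k + 1) * dt);
    }
  }
  return NumericVector::create(stage, x[3], tumax, settle);
}

// Batch settling times for Monte-Carlo / Sobol work: one row of `pars` and
// `x0s` per run, shared impulse schedule. Non-finite runs yield NA (caller
// decides how to treat them).
// [[Rcpp::export]]
NumericVector settle_batch_cpp(NumericMatrix pars, NumericMatrix x0s,
                               IntegerVector imp_idx, NumericVector imp_dose,
                               int kt, double dt, double frac) {
  const int n = pars.nrow();
  NumericVector out(n);
  std::vector<double> p(10);
  for (int run = 0; run < n; ++run) {
    double x[4];
    for (int i = 0; i < 10; ++i) p[i] = pars(run, i);
    for (int i = 0; i < 4; ++i) x[i] = x0s(run, i);
    const double thr = frac * x[3];
    R_xlen_t ni = imp_idx.size(), j = 0;
    double settle = NA_REAL;
    bool bad = false;
    for (int k = 0; k <= kt && !bad; ++k) {
      while (j < ni && imp_idx[j] == k) { x[0] += imp_dose[j]; ++j; }
      if (ISNA(settle) && x[3] < thr) { settle = k * dt; break; }
      if (k < kt) bad = !rk4(x, p.data(), dt);
    }
    out[run] = bad ? NA_REAL : settle;
    if (run % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Batch full-Tu curves for the uncertainty band: returns (kt+1) x n matrix
// of Tu(t) per run (thinned by `stride` to keep memory modest).
// [[Rcpp::export]]
NumericMatrix tu_curves_cpp(NumericMatrix pars, NumericMatrix x0s,
                            IntegerVector imp_idx, NumericVector imp_dose,
                            int kt, double dt, int stride) {
  const int n = pars.nrow();
  const int nrow = kt / stride + 1;
  NumericMatrix out(nrow, n);
  std::vector<double> p(10);
  for (int run = 0; run < n; ++run) {
    double x[4];
    for (int i = 0; i < 10; ++i) p[i] = pars(run, i);
    for (int i = 0; i < 4; ++i) x[i] = x0s(run, i);
    R_xlen_t ni = imp_idx.size(), j = 0;
    int row = 0;
    for (int k = 0; k <= kt; ++k) {
      while (j < ni && imp_idx[j] == k) { x[0] += imp_dose[j]; ++j; }
      if (k % stride == 0) out(row++, run) = x[3];
      if (k < kt) {
        if (!rk4(x, p.data(), dt))
          stop("integration blow-up in run %d at step %d", run + 1, k + 1);
      }
    }
    if (run % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
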