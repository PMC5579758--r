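#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Right-hand side of the reconstitution model.
//
// State X(t): CD4 concentration (cells/uL) at time t (days) after HSCT for a
// child aged age0 days at transplant.  Age advances with follow-up time
// (tau = age0 + t).  Thymic output is lambda0 * lambda_age(tau) * Delta(t),
// proliferation p0 * y(tau) * exp(cp (1 - X/N)) and loss
// d0 * y(tau) * exp(cd (X/N - 1)), both first order in X.
//
// params (natural scale): lambda0, d0, p0, x0, lambda_h, lambda_r, cp, cd
// consts: nt_asym, nt_amp, nt_rate, nn_asym, nn_amp, nn_rate,
//         ki67_0, ki67_rate, mult  (mult = frozen grouping multiplier so that
//         lambda_age(tau) = mult * y(tau) * Nn(tau))
static inline double cd4_rhs(double t, double X, const double* p,
                             double age0, const double* cs) {
  const double tau = age0 + t;
  const double N  = cs[0] + cs[1] * std::exp(-cs[2] * tau);
  const double Nn = cs[3] + cs[4] * std::exp(-cs[5] * tau);
  const double y  = cs[6] * std::exp(-cs[7] * tau);

  // sigmoidal recovery of thymic output, overflow-safe for large lambda_r
  const double num = 1.0 - std::exp(-2.0 * t / p[4]);
  const double z   = p[5] * (1.0 - t / p[4]);
  double delta;
  if (z > 700.0)      delta = num * std::exp(-z);
  else                delta = num / (1.0 + std::exp(z));

  const double lam = p[0] * cs[8] * y * Nn * delta;
  const double r   = X / N;
  const double d   = p[1] * y * std::exp(p[7] * (r - 1.0));
  const double pr  = p[2] * y * std::exp(p[6] * (1.0 - r));
  return lam - d * X + pr * X;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order embedded solution weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Integrate from t0 to t1, returning the state at t1 (NaN on failure).
static double integrate_to(double t0, double t1, double X,
                           const double* p, double age0, const double* cs,
                           double rtol, double atol) {
  if (t1 <= t0) return X;
  const double hmax = 25.0;     // never step over the sigmoid gate blindly
  double h = std::min(1.0, t1 - t0);
  double t = t0;
  double k1 = cd4_rhs(t, X, p, age0, cs);
  int nstep = 0;
  while (t < t1) {
    if (++nstep > 1000000) return NA_REAL;
    if (h > t1 - t) h = t1 - t;
    const double k2 = cd4_rhs(t + c2 * h, X + h * a21 * k1, p, age0, cs);
    const double k3 = cd4_rhs(t + c3 * h, X + h * (a31 * k1 + a32 * k2), p, age0, cs);
    const double k4 = cd4_rhs(t + c4 * h, X + h * (a41 * k1 + a42 * k2 + a43 * k3), p, age0, cs);
    const double k5 = cd4_rhs(t + c5 * h, X + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4), p, age0, cs);
    const double k6 = cd4_rhs(t + h, X + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5), p, age0, cs);
    const double X5 = X + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    const double k7 = cd4_rhs(t + h, X5, p, age0, cs);
    const double X4 = X + h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);
    const double sc  = atol + rtol * std::max(std::fabs(X), std::fabs(X5));
    const double err = std::fabs(X5 - X4) / sc;
    if (!std::isfinite(err)) return NA_REAL;
    if (err <= 1.0 && X5 > 0.0) {
      t += h;
      X = X5;
      k1 = k7;  // FSAL
      double fac = 0.9 * std::pow(err > 1e-12 ? err : 1e-12, -0.2);
      if (fac > 5.0) fac = 5.0;
      h = std::min(h * fac, hmax);
    } else {
      double fac = err > 1.0 ? std::max(0.2, 0.9 * std::pow(err, -0.2)) : 0.5;
      h *= fac;
      if (h < 1e-10) return NA_REAL;
    }
  }
  return X;
}

static void fill_solution(const double* p, double age0, const double* cs,
                          const double* times, int nt, double* out,
                          double rtol, double atol) {
  double X = p[3];  // X(0) = x0
  double t = 0.0;
  for (int i = 0; i < nt; ++i) {
    X = integrate_to(t, times[i], X, p, age0, cs, rtol, atol);
    t = times[i];
    out[i] = X;
    if (!std::isfinite(X)) {
      for (int j = i + 1; j < nt; ++j) out[j] = NA_REAL;
      return;
    }
  }
}

// [[Rcpp::export]]
NumericVector cd4_solve_cpp(NumericVector times, NumericVector params,
                            double age0, NumericVector consts,
                            double rtol = 1e-8, double atol = 1e-6) {
  const int nt = times.size();
  NumericVector out(nt);
  fill_solution(REAL(params), age0, REAL(consts), REAL(times), nt, REAL(out),
                rtol, atol);
  return out;
}

// Solve one trajectory per row of log_params (K x 6, log scale:
// lambda0, d0, p0, x0, lambda_h, lambda_r) at common output times.
// [[Rcpp::export]]
NumericMatrix cd4_solve_batch_cpp(NumericMatrix log_params, double age0,
                                  NumericVector times, NumericVector consts,
                                  double cp = 1.0, double cd = 1.0,
                                  double rtol = 1e-8, double atol = 1e-6) {
  const int K = log_params.nrow(), nt = times.size();
  NumericMatrix out(K, nt);
  std::vector<double> p(8), row(nt);
  p[6] = cp; p[7] = cd;
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < 6; ++j) p[j] = std::exp(log_params(k, j));
    fill_solution(p.data(), age0, REAL(consts), REAL(times), nt, row.data(),
                  rtol, atol);
    for (int i = 0; i < nt; ++i) out(k, i) = row[i];
  }
  return out;
}

// Gaussian log likelihood of log-transformed observations for each parameter
// row: sum_j dnorm(log_dv[j]; log X(t_j), sqrt(sigma2), log = TRUE).
// Rows whose trajectory cannot be solved (or hits zero) get -Inf.
// [[Rcpp::export]]
NumericVector cd4_loglik_cpp(NumericMatrix log_params, double age0,
                             NumericVector obs_times, NumericVector log_dv,
                             double sigma2, NumericVector consts,
                             double cp = 1.0, double cd = 1.0,
                             double rtol = 1e-8, double atol = 1e-6) {
  const int K = log_params.nrow(), nt = obs_times.size();
  NumericVector out(K);
  std::vector<double> p(8), x(nt);
  p[6] = cp; p[7] = cd;
  const double ln2pi = std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < 6; ++j) p[j] = std::exp(log_params(k, j));
    fill_solution(p.data(), age0, REAL(consts), REAL(obs_times), nt, x.data(),
                  rtol, atol);
    double ll = -0.5 * nt * (ln2pi + std::log(sigma2));
    for (int i = 0; i < nt; ++i) {
      if (!std::isfinite(x[i]) || x[i] <= 0.0) { ll = R_NegInf; break; }
      const double r = log_dv[i] - std::log(x[i]);
      ll -= 0.5 * r * r / sigma2;
    }
    out[k] = ll;
  }
  return out;
}
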