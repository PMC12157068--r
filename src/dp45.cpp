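#include <Rcpp.h>
#include <cmath>

// Scalar Dormand-Prince 5(4) integrator for the duckweed density ODEs.
// Model 0: canopy model  dD/dt = D * (E * r_phot_i * fbar(I_S, D) - r_resp)
//   with fbar the Beer-Lambert-averaged Monod limitation,
//   fbar = [ln(k + I_S) - ln(k + I_S * exp(-eps_hat * D))] / (eps_hat * D),
//   switching to the analytic Monod limit I_S/(k + I_S) when eps_hat*D < 1e-8
//   (0/0 cancellation below that threshold).
// Model 1: logistic comparator
//   dD/dt = D * (r_phot_i * (1 - D/h_D) * E * I/(K_I + I) - r_resp)

static const double SMALL_X = 1e-8;

static inline double fbar_canopy(double Is, double D, double eps_hat, double k) {
  double x = eps_hat * D;
  if (x < SMALL_X) return Is / (k + Is);
  // log(k+Is) - log(k+Is*exp(-x)) via log1p/expm1 avoids cancellation
  return std::log1p(Is * (-std::expm1(-x)) / (k + Is * std::exp(-x))) / x;
}

static inline double rhs(double D, double Is, const double* p, int model) {
  if (model == 0) {
    // p = {r_phot_i, r_resp, eps_hat, k, E}
    return D * (p[4] * p[0] * fbar_canopy(Is, D, p[2], p[3]) - p[1]);
  }
  // p = {r_phot_i, r_resp, h_D, K_I, E}
  return D * (p[0] * (1.0 - D / p[2]) * p[4] * Is / (p[3] + Is) - p[1]);
}

// Integrate from (t0, y0) to t1, adapting the step; returns y(t1).
static double dp45_advance(double t0, double t1, double y0, double Is,
                           const double* p, int model,
                           double rtol, double atol, double h_init,
                           double* h_next) {
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
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

  double t = t0, y = y0, h = h_init;
  double span = t1 - t0;
  if (span <= 0.0) { *h_next = h_init; return y0; }
  double hmin = 1e-13 * std::max(1.0, std::fabs(t1));
  if (h > span) h = span;
  int n_reject_run = 0;

  while (t < t1) {
    if (h > t1 - t) h = t1 - t;
    double k1 = rhs(y, Is, p, model);
    double k2 = rhs(y + h * a21 * k1, Is, p, model);
    double k3 = rhs(y + h * (a31 * k1 + a32 * k2), Is, p, model);
    double k4 = rhs(y + h * (a41 * k1 + a42 * k2 + a43 * k3), Is, p, model);
    double k5 = rhs(y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4), Is, p, model);
    double k6 = rhs(y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5),
                    Is, p, model);
    double y5 = y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    double k7 = rhs(y5, Is, p, model);
    double err = h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);
    double sc = atol + rtol * std::max(std::fabs(y), std::fabs(y5));
    double enorm = std::fabs(err) / sc;

    if (!std::isfinite(y5) || !std::isfinite(enorm)) {
      Rcpp::stop("integration failure: non-finite state at t = %g (D = %g)", t, y);
    }
    if (enorm <= 1.0) {
      t += h;
      y = y5;
      n_reject_run = 0;
      double fac = 0.9 * std::pow(enorm > 1e-30 ? 1.0 / enorm : 1e30, 0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(1.0 / enorm, 0.2);
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (++n_reject_run > 50 || h < hmin) {
        Rcpp::stop("integration failure: step collapse at t = %g (h = %g)", t, h);
      }
    }
    if (h < hmin) h = hmin;
  }
  *h_next = h;
  return y;
}

// [[Rcpp::export(name = ".cpp_simulate")]]
Rcpp::NumericVector cpp_simulate(double d0, double Is,
                                 Rcpp::NumericVector params, int model,
                                 Rcpp::NumericVector times,
                                 double rtol, double atol) {
  int n = times.size();
  Rcpp::NumericVector out(n);
  const double* p = params.begin();
  double y = d0, t = 0.0, h = 0.05;
  for (int i = 0; i < n; ++i) {
    if (times[i] > t) {
      y = dp45_advance(t, times[i], y, Is, p, model, rtol, atol, h, &h);
      t = times[i];
    }
    out[i] = y;
  }
  return out;
}

// Terminal densities for a batch of trials (the least-squares workhorse).
// [[Rcpp::export(name = ".cpp_terminal")]]
Rcpp::NumericVector cpp_terminal(Rcpp::NumericVector d0, Rcpp::NumericVector Is,
                                 Rcpp::NumericVector duration,
                                 Rcpp::NumericVector params, int model,
                                 double rtol, double atol) {
  int n = d0.size();
  Rcpp::NumericVector out(n);
  const double* p = params.begin();
  for (int i = 0; i < n; ++i) {
    double h = 0.05;
    out[i] = dp45_advance(0.0, duration[i], d0[i], Is[i], p, model,
                          rtol, atol, 0.05, &h);
  }
  return out;
}
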