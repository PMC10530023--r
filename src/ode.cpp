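#include <Rcpp.h>
#include "model.h"

using namespace Rcpp;

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
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

static ModelP unpack(const NumericVector& p, const IntegerVector& sw) {
  ModelP mp;
  mp.r = p[0]; mp.m = p[1]; mp.m_v = p[2]; mp.a = p[3]; mp.B = p[4];
  mp.c_R = p[5]; mp.tau = p[6]; mp.mu = p[7]; mp.A = p[8]; mp.L = p[9];
  mp.K = p[10];
  mp.per_capita_mutation = sw[0];
  mp.acquisition_from_R = sw[1];
  mp.rescue_on_acquisition = sw[2];
  return mp;
}

// [[Rcpp::export(name = ".ode_rhs_cpp")]]
NumericVector ode_rhs_cpp(NumericVector y, NumericVector p, IntegerVector sw) {
  ModelP mp = unpack(p, sw);
  NumericVector dy(5);
  model_rhs(y.begin(), mp, dy.begin());
  return dy;
}

// Integrate from times[0] to times[last], recording the state at every
// requested time. Steps never straddle an output time, so no dense-output
// interpolation is needed; the local error test keeps the recorded states
// at the requested tolerances.
// [[Rcpp::export(name = ".ode_integrate_cpp")]]
List ode_integrate_cpp(NumericVector y0, NumericVector p, IntegerVector sw,
                       NumericVector times, double rtol, double atol,
                       double max_step, int max_steps) {
  const int d = 5, nt = times.size();
  ModelP mp = unpack(p, sw);

  NumericMatrix out(nt, d);
  for (int j = 0; j < d; ++j) out(0, j) = y0[j];

  double y[5], ytmp[5], ynew[5];
  double k1[5], k2[5], k3[5], k4[5], k5[5], k6[5], k7[5];
  for (int j = 0; j < d; ++j) y[j] = y0[j];

  double t = times[0];
  double h = std::min(1e-3, max_step);
  long n_accept = 0, n_reject = 0;
  bool tol_warn = false;

  model_rhs(y, mp, k1); // FSAL seed

  for (int it = 1; it < nt; ++it) {
    double t_end = times[it];
    while (t < t_end) {
      if (n_accept + n_reject > (long)max_steps)
        stop("ODE integration exceeded max_steps (%d); diagnostics: t=%g, h=%g",
             max_steps, t, h);
      bool hit = false;
      if (t + h >= t_end) { h = t_end - t; hit = true; }

      for (int j = 0; j < d; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      model_rhs(ytmp, mp, k2);
      for (int j = 0; j < d; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      model_rhs(ytmp, mp, k3);
      for (int j = 0; j < d; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      model_rhs(ytmp, mp, k4);
      for (int j = 0; j < d; ++j)
        ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                              a54 * k4[j]);
      model_rhs(ytmp, mp, k5);
      for (int j = 0; j < d; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
      model_rhs(ytmp, mp, k6);
      for (int j = 0; j < d; ++j)
        ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                              b5 * k5[j] + b6 * k6[j]);
      model_rhs(ynew, mp, k7);

      // embedded error estimate
      double errnorm = 0.0;
      for (int j = 0; j < d; ++j) {
        double y4 = y[j] + h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                                e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
        double e = (ynew[j] - y4) / sc;
        errnorm += e * e;
      }
      errnorm = std::sqrt(errnorm / d);

      if (errnorm <= 1.0 || h <= 1e-14) {
        if (errnorm > 1.0) tol_warn = true;
        t = hit ? t_end : t + h;
        for (int j = 0; j < d; ++j) { y[j] = ynew[j]; k1[j] = k7[j]; }
        ++n_accept;
        double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
        h *= std::min(5.0, std::max(0.2, fac));
        if (h > max_step) h = max_step;
      } else {
        ++n_reject;
        h *= std::max(0.1, 0.9 * std::pow(errnorm, -0.2));
      }
      if (!R_finite(y[0]) || !R_finite(y[4]))
        stop("ODE integration produced non-finite state at t=%g", t);
    }
    for (int j = 0; j < d; ++j) out(it, j) = y[j];
  }

  return List::create(_["states"] = out, _["n_accept"] = (double)n_accept,
                      _["n_reject"] = (double)n_reject,
                      _["tolerance_warning"] = tol_warn);
}
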