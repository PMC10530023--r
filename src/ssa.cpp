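#include <Rcpp.h>
#include "model.h"

using namespace Rcpp;

// Event-based counterpart of the deterministic model on integer counts.
// Densities map to counts through `volume` (counts = density * volume);
// bimolecular encounters scale as a / volume. Propensities mirror the
// deterministic fluxes exactly, with the per-replication mutation model
// realised as a Bernoulli(mu) choice at S and C birth events and the
// logistic factor clipped at 0 when demographic noise overshoots K.
//
// Channel table (state change on (S, R, C, D, V)):
//  0 birth S            (+1, 0, 0, 0, 0)   rS*g*S*(1-muP)
//  1 birth S -> mutant  ( 0,+1, 0, 0, 0)   rS*g*S*muP
//  2 birth R            ( 0,+1, 0, 0, 0)   rR*g*R
//  3 birth C            ( 0, 0,+1, 0, 0)   rC*g*C*(1-muP)
//  4 birth C -> mutant  ( 0, 0, 0,+1, 0)   rC*g*C*muP
//  5 birth D            ( 0, 0, 0,+1, 0)   rD*g*D
//  6 lysis of S         (-1, 0, 0, 0,+B-1) ae*V*S (*(1-A) if rescue)
//  7 rescue acquisition (-1, 0,+1, 0,-1)   ae*V*S*A       (rescue mode)
//  8 free acquisition   (-1, 0,+1, 0, 0)   A*ae*V*S       (default mode)
//  9 acquisition from R ( 0,-1, 0,+1, 0)   A*ae*V*R       (optional)
// 10 adsorption to C    ( 0, 0, 0, 0,-1)   ae*V*C  (phage sink)
// 11 loss C -> S        (+1, 0,-1, 0, 0)   L*C
// 12 loss D -> R        ( 0,+1, 0,-1, 0)   L*D
// 13 mutation S -> R    (-1,+1, 0, 0, 0)   mu*S   (per_capita mode)
// 14 mutation C -> D    ( 0, 0,-1,+1, 0)   mu*C   (per_capita mode)
// 15..18 deaths of S,R,C,D at m*X; 19 phage decay at m_v*V

static const int NCH = 20;

struct StochCtx {
  ModelP p;
  double ae;      // a / volume
  double Kc;      // K * volume (carrying capacity in counts)
  double vol;
  int Bi;         // integer burst size
  double v[NCH][5];
};

static void init_ctx(StochCtx& c, const ModelP& p, double volume) {
  c.p = p;
  c.ae = p.a / volume;
  c.Kc = p.K * volume;
  c.vol = volume;
  c.Bi = (int)std::lround(p.B);
  static const double vtab[NCH][5] = {
    {+1, 0, 0, 0, 0}, { 0,+1, 0, 0, 0}, { 0,+1, 0, 0, 0},
    { 0, 0,+1, 0, 0}, { 0, 0, 0,+1, 0}, { 0, 0, 0,+1, 0},
    {-1, 0, 0, 0, 0}, {-1, 0,+1, 0,-1}, {-1, 0,+1, 0, 0},
    { 0,-1, 0,+1, 0}, { 0, 0, 0, 0,-1}, {+1, 0,-1, 0, 0},
    { 0,+1, 0,-1, 0}, {-1,+1, 0, 0, 0}, { 0, 0,-1,+1, 0},
    {-1, 0, 0, 0, 0}, { 0,-1, 0, 0, 0}, { 0, 0,-1, 0, 0},
    { 0, 0, 0,-1, 0}, { 0, 0, 0, 0,-1}};
  for (int j = 0; j < NCH; ++j)
    for (int i = 0; i < 5; ++i) c.v[j][i] = vtab[j][i];
  c.v[6][4] = p.B - 1.0; // lysis releases B, consumes 1
}

static void propensities(const StochCtx& c, const double* x, double* a,
                         bool& clipped) {
  const ModelP& p = c.p;
  const double S = x[0], R = x[1], C = x[2], D = x[3], V = x[4];
  double g = 1.0 - (S + R + C + D) / c.Kc;
  if (g < 0) { g = 0.0; clipped = true; }
  const double rS = p.r;
  const double rR = std::exp(-p.c_R) * p.r;
  const double rC = std::exp(-p.tau * p.a * (V / c.vol)) * p.r;
  const double muP = p.per_capita_mutation ? 0.0 : p.mu;

  a[0] = rS * g * S * (1.0 - muP);
  a[1] = rS * g * S * muP;
  a[2] = rR * g * R;
  a[3] = rC * g * C * (1.0 - muP);
  a[4] = rC * g * C * muP;
  a[5] = rR * g * D;
  const double adsS = c.ae * V * S;
  if (p.rescue_on_acquisition) {
    a[6] = adsS * (1.0 - p.A);
    a[7] = adsS * p.A;
    a[8] = 0.0;
  } else {
    a[6] = adsS;
    a[7] = 0.0;
    a[8] = p.A * adsS;
  }
  a[9] = p.acquisition_from_R ? p.A * c.ae * V * R : 0.0;
  a[10] = c.ae * V * C;
  a[11] = p.L * C;
  a[12] = p.L * D;
  a[13] = p.per_capita_mutation ? p.mu * S : 0.0;
  a[14] = p.per_capita_mutation ? p.mu * C : 0.0;
  a[15] = p.m * S;
  a[16] = p.m * R;
  a[17] = p.m * C;
  a[18] = p.m * D;
  a[19] = p.m_v * V;
}

static void fire(const StochCtx& c, double* x, int j, double n = 1.0) {
  for (int i = 0; i < 5; ++i) {
    x[i] += n * c.v[j][i];
    if (x[i] < 0) x[i] = 0; // guard against rounding in tau-leap bookkeeping
  }
}

// [[Rcpp::export(name = ".ssa_exact_cpp")]]
List ssa_exact_cpp(NumericVector x0, NumericVector p, IntegerVector sw,
                   NumericVector times, double volume, double max_events) {
  ModelP mp;
  mp.r = p[0]; mp.m = p[1]; mp.m_v = p[2]; mp.a = p[3]; mp.B = p[4];
  mp.c_R = p[5]; mp.tau = p[6]; mp.mu = p[7]; mp.A = p[8]; mp.L = p[9];
  mp.K = p[10];
  mp.per_capita_mutation = sw[0]; mp.acquisition_from_R = sw[1];
  mp.rescue_on_acquisition = sw[2];
  StochCtx c; init_ctx(c, mp, volume);

  const int nt = times.size();
  NumericMatrix out(nt, 5);
  double x[5], a[NCH];
  for (int i = 0; i < 5; ++i) { x[i] = x0[i]; out(0, i) = x0[i]; }
  double t = times[0];
  double n_events = 0; bool clipped = false;
  int it = 1;

  while (it < nt) {
    bool cl = false;
    propensities(c, x, a, cl);
    clipped = clipped || cl;
    double a0 = 0;
    for (int j = 0; j < NCH; ++j) a0 += a[j];
    double t_next = (a0 > 0) ? t + exp_rand() / a0 : R_PosInf;
    while (it < nt && times[it] <= t_next) {
      for (int i = 0; i < 5; ++i) out(it, i) = x[i];
      ++it;
    }
    if (it >= nt || a0 <= 0) break;
    t = t_next;
    double u = unif_rand() * a0, acc = 0;
    int j = 0;
    for (; j < NCH - 1; ++j) { acc += a[j]; if (u <= acc) break; }
    fire(c, x, j);
    if (++n_events > max_events)
      stop("exact SSA exceeded max_events (%.0f); use method='tau_leap'",
           max_events);
  }
  return List::create(_["states"] = out, _["n_events"] = n_events,
                      _["rate_clipped"] = clipped);
}

// Adaptive tau-leaping with Cao's step-size bound (bounded relative change
// in propensities, eps = 0.03) and fallback to exact steps when the leap
// would be smaller than a few event times.
// [[Rcpp::export(name = ".ssa_tau_leap_cpp")]]
List ssa_tau_leap_cpp(NumericVector x0, NumericVector p, IntegerVector sw,
                      NumericVector times, double volume, double eps) {
  ModelP mp;
  mp.r = p[0]; mp.m = p[1]; mp.m_v = p[2]; mp.a = p[3]; mp.B = p[4];
  mp.c_R = p[5]; mp.tau = p[6]; mp.mu = p[7]; mp.A = p[8]; mp.L = p[9];
  mp.K = p[10];
  mp.per_capita_mutation = sw[0]; mp.acquisition_from_R = sw[1];
  mp.rescue_on_acquisition = sw[2];
  StochCtx c; init_ctx(c, mp, volume);

  const int nt = times.size();
  NumericMatrix out(nt, 5);
  double x[5], a[NCH], k[NCH];
  for (int i = 0; i < 5; ++i) { x[i] = x0[i]; out(0, i) = x0[i]; }
  double t = times[0];
  double n_leaps = 0, n_exact = 0; bool clipped = false;
  int it = 1;

  while (it < nt) {
    bool cl = false;
    propensities(c, x, a, cl);
    clipped = clipped || cl;
    double a0 = 0;
    for (int j = 0; j < NCH; ++j) a0 += a[j];
    if (a0 <= 0) break;

    // Cao bound: tau = min_i max(eps*x_i, 1) / |mu_i|, (eps*x_i)^2 / sig_i
    double tau = R_PosInf;
    for (int i = 0; i < 5; ++i) {
      double mu_i = 0, sig_i = 0;
      for (int j = 0; j < NCH; ++j) {
        mu_i += c.v[j][i] * a[j];
        sig_i += c.v[j][i] * c.v[j][i] * a[j];
      }
      double bnd = std::max(eps * x[i], 1.0);
      if (mu_i != 0) tau = std::min(tau, bnd / std::fabs(mu_i));
      if (sig_i > 0) tau = std::min(tau, bnd * bnd / sig_i);
    }

    if (tau < 10.0 / a0) {
      // leap not worthwhile: take up to 50 exact steps
      for (int s = 0; s < 50 && it < nt; ++s) {
        bool cl2 = false;
        propensities(c, x, a, cl2);
        clipped = clipped || cl2;
        a0 = 0;
        for (int j = 0; j < NCH; ++j) a0 += a[j];
        double t_next = (a0 > 0) ? t + exp_rand() / a0 : R_PosInf;
        while (it < nt && times[it] <= t_next) {
          for (int i = 0; i < 5; ++i) out(it, i) = x[i];
          ++it;
        }
        if (it >= nt || a0 <= 0) { t = t_next; break; }
        t = t_next;
        double u = unif_rand() * a0, acc = 0;
        int j = 0;
        for (; j < NCH - 1; ++j) { acc += a[j]; if (u <= acc) break; }
        fire(c, x, j);
        ++n_exact;
      }
      if (a0 <= 0) break;
      continue;
    }

    for (;;) {
      if (t + tau > times[it]) tau = times[it] - t;
      bool ok = true;
      double xn[5] = {x[0], x[1], x[2], x[3], x[4]};
      for (int j = 0; j < NCH; ++j)
        k[j] = (a[j] > 0) ? R::rpois(a[j] * tau) : 0.0;
      for (int j = 0; j < NCH; ++j)
        if (k[j] > 0)
          for (int i = 0; i < 5; ++i) xn[i] += k[j] * c.v[j][i];
      for (int i = 0; i < 5; ++i) if (xn[i] < 0) ok = false;
      if (ok) {
        for (int i = 0; i < 5; ++i) x[i] = xn[i];
        t += tau;
        ++n_leaps;
        break;
      }
      tau *= 0.5; // redraw with a smaller leap
    }
    while (it < nt && times[it] <= t) {
      for (int i = 0; i < 5; ++i) out(it, i) = x[i];
      ++it;
    }
  }
  while (it < nt) {
    for (int i = 0; i < 5; ++i) out(it, i) = x[i];
    ++it;
  }
  return List::create(_["states"] = out, _["n_leaps"] = n_leaps,
                      _["n_exact"] = n_exact, _["rate_clipped"] = clipped);
}
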