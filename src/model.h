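#ifndef CRISPRDYN_MODEL_H
#define CRISPRDYN_MODEL_H

#include <cmath>

// Parameter layout shared by the deterministic and stochastic engines.
// Order must match the R-side param_vector() helper.
struct ModelP {
  double r, m, m_v, a, B, c_R, tau, mu, A, L, K;
  int per_capita_mutation;   // 0 = per_replication (default), 1 = per_capita
  int acquisition_from_R;    // surface mutants can also pick up spacers
  int rescue_on_acquisition; // acquisition subtracts from the lysis flux
};

// Five-compartment RHS: y = (S, R, C, D, V).
// g = 1 - N/K is deliberately not clipped (valid initial conditions with
// m = 0 keep N <= K up to solver error).
inline void model_rhs(const double* y, const ModelP& p, double* dy) {
  const double S = y[0], R = y[1], C = y[2], D = y[3], V = y[4];
  const double N = S + R + C + D;
  const double g = 1.0 - N / p.K;

  const double rS = p.r;
  const double rR = std::exp(-p.c_R) * p.r;
  const double rC = std::exp(-p.tau * p.a * V) * p.r;
  const double rD = rR;

  const double MS = p.per_capita_mutation ? p.mu * S : p.mu * rS * g * S;
  const double MC = p.per_capita_mutation ? p.mu * C : p.mu * rC * g * C;

  const double adsS = p.a * V * S;               // phage removed on S
  const double lysS = p.rescue_on_acquisition ? (1.0 - p.A) * adsS : adsS;
  const double acqS = p.A * p.a * V * S;
  const double acqR = p.acquisition_from_R ? p.A * p.a * V * R : 0.0;

  dy[0] = rS * g * S - lysS - MS - acqS + p.L * C - p.m * S;
  dy[1] = rR * g * R + MS + p.L * D - p.m * R - acqR;
  dy[2] = rC * g * C + acqS - MC - p.L * C - p.m * C;
  dy[3] = rD * g * D + MC - p.L * D - p.m * D + acqR;
  dy[4] = p.B * lysS - p.a * V * (S + C) - p.m_v * V;
}

#endif
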