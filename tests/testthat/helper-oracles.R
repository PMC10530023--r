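# Independent oracles used across the suite. These deliberately do not call
# the package's numerical paths they are checking.

# closed-form logistic growth
logistic_closed_form <- function(t, S0, r, K) {
  K * S0 * exp(r * t) / (K + S0 * (exp(r * t) - 1))
}

# fixed-step Euler re-implementation of the serial-transfer protocol,
# written directly from the model equations (default switches only)
euler_protocol <- function(S0, V0, params, n_transfers = 3, hours = 20,
                           dilution = 0.01, dt = 1e-3) {
  r <- params$r; m <- params$m; m_v <- params$m_v; a <- params$a
  B <- params$B; c_R <- params$c_R; tau <- params$tau; mu <- params$mu
  A <- params$A; L <- params$L; K <- params$K
  y <- c(S = S0, R = 0, C = 0, D = 0, V = V0)
  for (k in seq_len(n_transfers)) {
    for (i in seq_len(round(hours / dt))) {
      S <- y[1]; R <- y[2]; C <- y[3]; D <- y[4]; V <- y[5]
      g <- 1 - (S + R + C + D) / K
      rR <- exp(-c_R) * r
      rC <- exp(-tau * a * V) * r
      MS <- mu * r * g * S
      MC <- mu * rC * g * C
      dS <- r * g * S - a * V * S - MS - A * a * V * S + L * C - m * S
      dR <- rR * g * R + MS + L * D - m * R
      dC <- rC * g * C + A * a * V * S - MC - L * C - m * C
      dD <- rR * g * D + MC - L * D - m * D
      dV <- B * a * V * S - a * V * (S + C) - m_v * V
      y <- y + dt * c(dS, dR, dC, dD, dV)
    }
    if (k < n_transfers) y <- y * c(rep(dilution, 4), dilution)
  }
  y
}

# independent plain-R Gillespie for the stochastic engine (counts, volume
# scaling), coded from the model description rather than the C++ source
r_gillespie <- function(x0, params, duration, volume = 1) {
  ae <- params$a / volume
  Kc <- params$K * volume
  x <- x0  # c(S, R, C, D, V)
  t <- 0
  repeat {
    S <- x[1]; R <- x[2]; C <- x[3]; D <- x[4]; V <- x[5]
    g <- max(0, 1 - (S + R + C + D) / Kc)
    rR <- exp(-params$c_R) * params$r
    rC <- exp(-params$tau * params$a * (V / volume)) * params$r
    rates <- c(bS = params$r * g * S * (1 - params$mu),
               bSmut = params$r * g * S * params$mu,
               bR = rR * g * R,
               bC = rC * g * C * (1 - params$mu),
               bCmut = rC * g * C * params$mu,
               bD = rR * g * D,
               lys = ae * V * S,
               acq = params$A * ae * V * S,
               adsC = ae * V * C,
               lossC = params$L * C,
               lossD = params$L * D)
    a0 <- sum(rates)
    if (a0 <= 0) break
    t <- t + rexp(1, a0)
    if (t > duration) break
    ev <- sample(names(rates), 1, prob = rates)
    x <- x + switch(ev,
      bS = c(1, 0, 0, 0, 0), bSmut = c(0, 1, 0, 0, 0),
      bR = c(0, 1, 0, 0, 0), bC = c(0, 0, 1, 0, 0),
      bCmut = c(0, 0, 0, 1, 0), bD = c(0, 0, 0, 1, 0),
      lys = c(-1, 0, 0, 0, params$B - 1), acq = c(-1, 0, 1, 0, 0),
      adsC = c(0, 0, 0, 0, -1), lossC = c(1, 0, -1, 0, 0),
      lossD = c(0, 1, 0, -1, 0))
  }
  x
}

# multinomial log-pmf summation, coded independently of clone_loglikelihood
r_multinom_ll <- function(tab, probs_by_key) {
  ll <- 0
  for (i in seq_len(nrow(tab))) {
    x <- as.numeric(tab[i, c("n_sensitive", "n_sm", "n_crispr")])
    p <- pmax(probs_by_key[[paste(tab$treatment[i], tab$day[i])]], 1e-12)
    ll <- ll + lfactorial(sum(x)) - sum(lfactorial(x)) + sum(x * log(p))
  }
  ll
}

# build a pop_state from a named numeric row (states-matrix row)
as_pop_state_test <- function(x) {
  pop_state(S = x[["S"]], R = x[["R"]], C = x[["C"]], D = x[["D"]],
            V = x[["V"]])
}

# random valid population state (N <= K) for property tests
random_state <- function(K = 1e8) {
  f <- runif(4)
  f <- f / sum(f) * runif(1, 0.1, 1)
  pop_state(S = f[1] * K, R = f[2] * K, C = f[3] * K, D = f[4] * K,
            V = 10^runif(1, 0, 9))
}

paper_params <- function(...) model_params(...)
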