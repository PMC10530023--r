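#' Stochastic (finite-population) simulation of the model
#'
#' Event-based counterpart of the deterministic system, on integer counts.
#' Densities are converted to counts through `volume` (counts = density x
#' volume; default 1 ml so densities equal counts). Events mirror the
#' deterministic fluxes: logistic births per genotype with the
#' per-replication mutation realised as a Bernoulli(`mu`) choice at S and C
#' births, mass-action adsorption to S with lysis and a burst of `B` phage,
#' infection-dependent spacer acquisition, adsorption to CRISPR-immune
#' cells removing phage without progeny (phage sink), CRISPR loss, and
#' background deaths. The logistic factor is clipped at 0 when demographic
#' noise overshoots `K` (flagged in the result). Serial transfers, if a
#' protocol is given, are binomial thinning with the protocol's dilution
#' factors.
#'
#' @param state0 initial [pop_state()] in densities; counts after volume
#'   scaling must be integers.
#' @param params a [model_params()].
#' @param duration hours to simulate (ignored if `protocol` is given: the
#'   protocol fixes the total duration).
#' @param seed integer seed; a single RNG stream per run.
#' @param method `"exact"` (Gillespie) or `"tau_leap"` (adaptive leaps with
#'   a bounded relative propensity change, falling back to exact steps when
#'   leaping is not worthwhile).
#' @param volume ml of culture represented (default 1).
#' @param n_out number of recorded time points per batch.
#' @param protocol optional [transfer_protocol()] for serial transfers.
#' @param max_events event budget for the exact method.
#' @param eps tau-leap accuracy parameter (bounded relative propensity
#'   change).
#' @return Object of class `stochastic_run`: list with `times`, integer
#'   `states` (counts), `seed`, `method`, `volume`, `n_events`,
#'   `rate_clipped` and `boundaries` (if a protocol was used).
#' @examples
#' p <- model_params(K = 1e5)
#' run <- simulate_stochastic(pop_state(S = 1e3, V = 100), p,
#'                            duration = 20, seed = 1)
#' tail(run$states, 1)
#' @export
simulate_stochastic <- function(state0, params, duration = 20, seed = 1,
                                method = c("exact", "tau_leap"), volume = 1,
                                n_out = 101, protocol = NULL,
                                max_events = 5e8, eps = 0.03) {
  stopifnot(inherits(params, "model_params"))
  method <- match.arg(method)
  state0 <- as_pop_state(state0, attr(state0, "t") %||% 0)
  x0 <- unclass(state0) * volume
  if (any(abs(x0 - round(x0)) > 1e-8))
    stop("simulate_stochastic: initial counts (density * volume) must be ",
         "integers", call. = FALSE)
  x0 <- round(x0)
  set.seed(seed)

  run_one <- function(x, t0, dur) {
    times <- seq(t0, t0 + dur, length.out = max(2L, n_out))
    res <- if (method == "exact")
      .ssa_exact_cpp(as.numeric(x), param_vector(params),
                     switch_vector(params), times, volume, max_events)
    else
      .ssa_tau_leap_cpp(as.numeric(x), param_vector(params),
                        switch_vector(params), times, volume, eps)
    colnames(res$states) <- c("S", "R", "C", "D", "V")
    res$times <- times
    res
  }

  if (is.null(protocol)) {
    res <- run_one(x0, attr(state0, "t"), duration)
    if (isTRUE(res$rate_clipped))
      warning("simulate_stochastic: logistic rate clipped at 0 ",
              "(demographic overshoot of K)")
    return(structure(list(times = res$times, states = res$states,
                          boundaries = nrow(res$states), seed = seed,
                          method = method, volume = volume,
                          n_events = res$n_events %||% NA_real_,
                          rate_clipped = isTRUE(res$rate_clipped)),
                     class = "stochastic_run"))
  }

  stopifnot(inherits(protocol, "transfer_protocol"))
  x <- x0
  t0 <- attr(state0, "t")
  times <- numeric(0); states <- NULL; boundaries <- integer(0)
  n_events <- 0; clipped <- FALSE
  for (k in seq_len(protocol$n_transfers)) {
    res <- run_one(x, t0, protocol$hours_per_transfer)
    keep <- if (k == 1) seq_along(res$times) else -1L
    times <- c(times, res$times[keep])
    states <- rbind(states, res$states[keep, , drop = FALSE])
    boundaries <- c(boundaries, nrow(states))
    n_events <- n_events + (res$n_events %||% 0)
    clipped <- clipped || isTRUE(res$rate_clipped)
    xe <- res$states[nrow(res$states), ]
    x <- c(thin_binomial(xe[1:4], protocol$dilution),
           thin_binomial(xe[5], protocol$phage_dilution))
    t0 <- t0 + protocol$hours_per_transfer
  }
  if (clipped)
    warning("simulate_stochastic: logistic rate clipped at 0 ",
            "(demographic overshoot of K)")
  structure(list(times = times, states = states, boundaries = boundaries,
                 seed = seed, method = method, volume = volume,
                 n_events = n_events, rate_clipped = clipped),
            class = "stochastic_run")
}

# binomial thinning; normal approximation far beyond rbinom's integer range
thin_binomial <- function(n, p) {
  if (p >= 1) return(n)
  vapply(n, function(ni) {
    if (ni <= 0) return(0)
    if (ni < 2^31 - 1) return(rbinom(1L, as.integer(ni), p))
    mu <- ni * p
    max(0, round(mu + sqrt(ni * p * (1 - p)) * rnorm(1L)))
  }, numeric(1))
}

#' @export
print.stochastic_run <- function(x, ...) {
  cat(sprintf("Stochastic run (%s, seed %d, volume %g ml): %d samples, %s events\n",
              x$method, x$seed, x$volume, length(x$times),
              format(x$n_events, big.mark = ",")))
  print(x$states[nrow(x$states), ])
  invisible(x)
}

#' Ensemble of stochastic replicates with a summary
#'
#' Runs `n` independent stochastic realisations (replicate `i` is seeded
#' `seed_base + i`) and summarises the final state across runs.
#'
#' @inheritParams simulate_stochastic
#' @param n number of replicate runs.
#' @param seed_base base seed; replicate `i` uses `seed_base + i`.
#' @param ... passed to [simulate_stochastic()].
#' @return List with `runs` (list of `stochastic_run`), and `summary`: a
#'   data.frame of mean, SD and standard error for the final S, R, C, D, V,
#'   total hosts N and the CRISPR frequency f_C.
#' @export
simulate_stochastic_ensemble <- function(n, state0, params, duration = 20,
                                         seed_base = 0, ...) {
  runs <- lapply(seq_len(n), function(i)
    simulate_stochastic(state0, params, duration = duration,
                        seed = seed_base + i, ...))
  fin <- t(vapply(runs, function(r) {
    x <- r$states[nrow(r$states), ]
    N <- sum(x[c("S", "R", "C", "D")])
    c(x, N = N, f_C = if (N > 0) x[["C"]] / N else NA_real_)
  }, numeric(7)))
  summ <- data.frame(variable = colnames(fin),
                     mean = colMeans(fin),
                     sd = apply(fin, 2, sd),
                     se = apply(fin, 2, sd) / sqrt(n), row.names = NULL)
  list(runs = runs, finals = fin, summary = summ)
}
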