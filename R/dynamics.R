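#' Serial-transfer protocol
#'
#' Defaults mirror the experimental protocol: 1:100 subculture daily for
#' 3 days, 20 hours of batch growth between transfers, with phage carried
#' along at the same 1:100 dilution.
#'
#' @param n_transfers number of growth periods.
#' @param hours_per_transfer duration of each batch growth period (h).
#' @param dilution factor applied to all host compartments at transfer,
#'   in (0, 1].
#' @param phage_dilution factor applied to free phage at transfer.
#' @return An object of class `transfer_protocol`.
#' @examples
#' transfer_protocol()                    # 3 x 20 h, 1:100
#' transfer_protocol(n_transfers = 1)     # single batch
#' @export
transfer_protocol <- function(n_transfers = 3, hours_per_transfer = 20,
                              dilution = 0.01, phage_dilution = 0.01) {
  if (n_transfers < 1 || n_transfers != round(n_transfers))
    stop("n_transfers must be a positive integer", call. = FALSE)
  if (hours_per_transfer <= 0)
    stop("hours_per_transfer must be > 0", call. = FALSE)
  if (dilution <= 0 || dilution > 1 || phage_dilution <= 0 ||
      phage_dilution > 1)
    stop("dilution factors must be in (0, 1]", call. = FALSE)
  structure(list(n_transfers = as.integer(n_transfers),
                 hours_per_transfer = hours_per_transfer,
                 dilution = dilution, phage_dilution = phage_dilution),
            class = "transfer_protocol")
}

#' @export
print.transfer_protocol <- function(x, ...) {
  cat(sprintf("Serial-transfer protocol: %d x %g h, host dilution %g, phage dilution %g\n",
              x$n_transfers, x$hours_per_transfer, x$dilution,
              x$phage_dilution))
  invisible(x)
}

#' Apply a serial-transfer dilution to a population state
#'
#' Hosts are multiplied by `dilution` and phage by `phage_dilution`; time
#' and the media carrying capacity are untouched (K is a property of the
#' fresh media). Genotype frequencies are invariant because the dilution is
#' genotype-blind.
#'
#' @param state a [pop_state()].
#' @param protocol a [transfer_protocol()].
#' @return The diluted [pop_state()].
#' @export
apply_transfer <- function(state, protocol) {
  state <- as_pop_state(state, attr(state, "t") %||% 0)
  x <- unclass(state)
  pop_state(x[["S"]] * protocol$dilution, x[["R"]] * protocol$dilution,
            x[["C"]] * protocol$dilution, x[["D"]] * protocol$dilution,
            x[["V"]] * protocol$phage_dilution, t = attr(state, "t"))
}

#' Solver options for the deterministic integrator
#'
#' @param rtol relative tolerance (default 1e-8: phage densities span
#'   ~10 orders of magnitude across treatments).
#' @param atol absolute tolerance (default 1e-12).
#' @param max_step largest step size in hours.
#' @param max_steps step budget before the integration aborts.
#' @param n_out number of equally spaced sample times per batch.
#' @param extinction_floor densities below this value are snapped to 0 at
#'   the end of each batch (the deterministic model has no absorbing
#'   extinction otherwise).
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(rtol = 1e-8, atol = 1e-12, max_step = Inf,
                           max_steps = 1e6, n_out = 201,
                           extinction_floor = 1e-30) {
  structure(list(rtol = rtol, atol = atol, max_step = max_step,
                 max_steps = as.integer(max_steps), n_out = as.integer(n_out),
                 extinction_floor = extinction_floor),
            class = "solver_options")
}

#' Integrate one batch-culture growth period
#'
#' Adaptive Dormand-Prince RK45 integration of the five-compartment system
#' over `duration` hours, recording `n_out` equally spaced states.
#'
#' @param state0 initial [pop_state()].
#' @param params a [model_params()].
#' @param duration batch duration in hours (> 0).
#' @param control a [solver_options()] list.
#' @return A `trajectory`: list with `times`, a `states` matrix (columns
#'   S, R, C, D, V), `boundaries` (indices of transfer boundaries),
#'   `params` and `solver` metadata.
#' @examples
#' tr <- integrate_batch(pop_state(S = 1e6, V = 1e4), model_params(), 20)
#' tail(tr$states, 1)
#' @export
integrate_batch <- function(state0, params, duration,
                            control = solver_options()) {
  stopifnot(inherits(params, "model_params"))
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  state0 <- as_pop_state(state0, attr(state0, "t") %||% 0)
  t0 <- attr(state0, "t")
  times <- seq(t0, t0 + duration, length.out = max(2L, control$n_out))
  res <- .ode_integrate_cpp(as.numeric(unclass(state0)),
                            param_vector(params), switch_vector(params),
                            times, control$rtol, control$atol,
                            control$max_step, control$max_steps)
  states <- res$states
  colnames(states) <- c("S", "R", "C", "D", "V")
  states[states < control$extinction_floor & states > 0] <- 0
  if (isTRUE(res$tolerance_warning))
    warning("integrate_batch: local error tolerance not met on some steps")
  new_trajectory(times, states, boundaries = nrow(states), params = params,
                 solver = list(rtol = control$rtol, atol = control$atol,
                               n_accept = res$n_accept,
                               n_reject = res$n_reject,
                               tolerance_warning = res$tolerance_warning))
}

new_trajectory <- function(times, states, boundaries, params, solver,
                           protocol = NULL, boundary_states = NULL) {
  structure(list(times = times, states = states,
                 boundaries = as.integer(boundaries), params = params,
                 protocol = protocol, boundary_states = boundary_states,
                 solver = solver),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples over t = [%g, %g] h, %d transfer boundar%s\n",
              length(x$times), min(x$times), max(x$times),
              length(x$boundaries),
              if (length(x$boundaries) == 1) "y" else "ies"))
  cat("Final state:\n")
  print(x$states[nrow(x$states), ])
  invisible(x)
}

#' Final state of a trajectory
#' @param traj a `trajectory`.
#' @return The last recorded [pop_state()] (pre-dilution at the last
#'   boundary).
#' @export
final_state <- function(traj) {
  n <- nrow(traj$states)
  as_pop_state(traj$states[n, ], t = traj$times[n])
}

#' Run a full serial-transfer protocol
#'
#' Concatenates batch integrations separated by [apply_transfer()]. Recorded
#' states at transfer boundaries are the end-of-batch (pre-dilution) states,
#' mirroring daily plating before subculture; the post-dilution states that
#' seed each next batch are kept in `boundary_states`.
#'
#' @inheritParams integrate_batch
#' @param protocol a [transfer_protocol()].
#' @return A `trajectory` spanning all transfers, with `boundaries` marking
#'   the end of each batch.
#' @examples
#' p <- model_params()
#' tr <- run_protocol(pop_state(S = 1e6, V = 1e4), p, transfer_protocol())
#' genotype_frequencies(final_state(tr))
#' @export
run_protocol <- function(state0, params, protocol = transfer_protocol(),
                         control = solver_options()) {
  stopifnot(inherits(protocol, "transfer_protocol"))
  state <- as_pop_state(state0, attr(state0, "t") %||% 0)
  times <- numeric(0)
  states <- NULL
  boundaries <- integer(0)
  bstates <- NULL
  n_accept <- n_reject <- 0
  tol_warn <- FALSE
  for (k in seq_len(protocol$n_transfers)) {
    tr <- integrate_batch(state, params, protocol$hours_per_transfer,
                          control = control)
    keep <- if (k == 1) seq_along(tr$times) else -1L
    times <- c(times, tr$times[keep])
    states <- rbind(states, tr$states[keep, , drop = FALSE])
    boundaries <- c(boundaries, nrow(states))
    n_accept <- n_accept + tr$solver$n_accept
    n_reject <- n_reject + tr$solver$n_reject
    tol_warn <- tol_warn || isTRUE(tr$solver$tolerance_warning)
    state <- apply_transfer(final_state(tr), protocol)
    bstates <- rbind(bstates, c(t = attr(state, "t"),
                                as.numeric(unclass(state))))
  }
  colnames(bstates) <- c("t", "S", "R", "C", "D", "V")
  new_trajectory(times, states, boundaries, params,
                 solver = list(rtol = control$rtol, atol = control$atol,
                               n_accept = n_accept, n_reject = n_reject,
                               tolerance_warning = tol_warn),
                 protocol = protocol, boundary_states = bstates)
}
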