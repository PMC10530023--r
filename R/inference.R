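#' Multinomial log-likelihood of a clone table under the deterministic model
#'
#' For each clone-table row, the observed (sensitive, sm, crispr) counts are
#' scored against a multinomial whose class probabilities are the
#' deterministic model's `(f_S, f_R + f_D, f_C)` at that treatment and day
#' (double mutants score as sm in the streak assay). Probabilities are
#' floored at 1e-12 before logging.
#'
#' @param params a [model_params()].
#' @param design an [experiment_design()] covering every treatment/day in
#'   the table.
#' @param clone_table a `clone_table` (or data.frame with columns
#'   `treatment`, `day`, `n_sensitive`, `n_sm`, `n_crispr`).
#' @param grid optional precomputed [run_design_grid()] result for `params`
#'   (to avoid re-integration).
#' @return Scalar log-likelihood.
#' @export
clone_loglikelihood <- function(params, design, clone_table, grid = NULL) {
  if (nrow(clone_table) == 0) return(0)
  if (is.null(grid)) grid <- run_design_grid(design, params)
  key_g <- paste(grid$treatment, grid$day)
  key_t <- paste(clone_table$treatment, clone_table$day)
  idx <- match(key_t, key_g)
  if (anyNA(idx))
    stop("clone_loglikelihood: table rows not covered by the design: ",
         paste(unique(key_t[is.na(idx)]), collapse = "; "), call. = FALSE)
  P <- cbind(grid$f_S, grid$f_R + grid$f_D, grid$f_C)[idx, , drop = FALSE]
  P <- pmax(P, 1e-12)
  X <- as.matrix(clone_table[, c("n_sensitive", "n_sm", "n_crispr")])
  n <- rowSums(X)
  sum(lgamma(n + 1) - rowSums(lgamma(X + 1)) + rowSums(X * log(P)))
}

#' Fit model parameters to clone tables by maximum likelihood
#'
#' Multi-start bounded optimisation (L-BFGS-B) in log10-parameter space of a
#' subset of `{mu, A, c_R, tau}` under the multinomial observation model of
#' [clone_loglikelihood()]. The deterministic model supplies the fitted
#' class frequencies (a mean-field approximation chosen for optimisation
#' cost). The first start is at the fixed parameter values; remaining
#' starts are drawn uniformly in log-space within the bounds.
#'
#' @param clone_table observed (or synthetic) clone counts.
#' @param design the [experiment_design()] that produced them. Fitting `A`
#'   or `mu` needs at least two treatments differing in `V0` or inoculum.
#' @param free character subset of `c("mu", "A", "c_R", "tau")`; empty for
#'   evaluation mode (returns the fixed parameters and their likelihood).
#' @param fixed a [model_params()] providing every non-free parameter (and
#'   the starting point of the first optimiser start).
#' @param bounds named list of `c(lower, upper)` per free parameter;
#'   default `[1e-8, 1e-1]` for all.
#' @param seed seed for the random starts (and bootstrap, if any).
#' @param n_starts number of optimiser starts.
#' @param n_boot optional nonparametric bootstrap over replicates for
#'   percentile intervals (0 = none).
#' @param control a [solver_options()].
#' @return Object of class `crispr_fit` with components `estimates`,
#'   `logLik`, `starts` (all starts and their optima), `fixed`, `free`,
#'   `bounds`, `convergence`, `boot` (matrix of bootstrap estimates or
#'   NULL), `seed`.
#' @examples
#' \donttest{
#' des <- bundled_design("inoculum_sweep")
#' ds <- generate_dataset(des, model_params(), noise = list(count_cv = 0),
#'                        seed = 3)
#' fit <- fit_parameters(ds$clones, des, free = "mu", seed = 3, n_starts = 2)
#' coef(fit)
#' }
#' @export
fit_parameters <- function(clone_table, design,
                           free = c("mu", "A"),
                           fixed = model_params(),
                           bounds = NULL, seed = 1, n_starts = 4,
                           n_boot = 0, control = solver_options()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(fixed, "model_params"))
  allowed <- c("mu", "A", "c_R", "tau")
  if (!all(free %in% allowed))
    stop("fit_parameters: free must be a subset of ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if ((("mu" %in% free) || ("A" %in% free)) &&
      nrow(unique(design$treatments[c("V0", "inoculum_fraction")])) < 2 &&
      length(design$sampling_days) < 2)
    stop("fit_parameters: design not identifiable for mu/A (needs >= 2 ",
         "treatments varying V0 or inoculum, or multiple days)",
         call. = FALSE)

  default_bounds <- stats::setNames(
    rep(list(c(1e-8, 1e-1)), length(free)), free)
  bounds <- modifyList(default_bounds, bounds %||% list())

  negll <- function(theta) {
    p <- fixed
    p[free] <- as.list(10^theta)
    -clone_loglikelihood(p, design, clone_table)
  }

  ll_fixed <- clone_loglikelihood(fixed, design, clone_table)
  if (length(free) == 0) {
    return(structure(list(estimates = numeric(0), logLik = ll_fixed,
                          starts = NULL, fixed = fixed, free = free,
                          bounds = bounds, convergence = 0L, boot = NULL,
                          seed = seed),
                     class = "crispr_fit"))
  }

  lo <- log10(vapply(bounds[free], `[`, numeric(1), 1))
  hi <- log10(vapply(bounds[free], `[`, numeric(1), 2))
  set.seed(seed)
  starts <- rbind(pmin(pmax(log10(unlist(fixed[free])), lo), hi),
                  if (n_starts > 1)
                    matrix(runif((n_starts - 1) * length(free),
                                 rep(lo, each = n_starts - 1),
                                 rep(hi, each = n_starts - 1)),
                           ncol = length(free)))

  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fits[[i]] <- tryCatch(
      optim(starts[i, ], negll, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 200)),
      error = function(e) list(value = Inf, par = starts[i, ],
                               convergence = 99L, message = conditionMessage(e)))
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  if (all(!is.finite(vals)))
    stop("fit_parameters: optimiser failed to converge in all starts",
         call. = FALSE)
  best <- fits[[which.min(vals)]]
  est <- setNames(10^best$par, free)
  starts_tab <- data.frame(starts, logLik = -vals,
                           converged = vapply(fits, function(f)
                             identical(f$convergence, 0L), logical(1)))
  names(starts_tab)[seq_along(free)] <- paste0("log10_", free, "_start")

  boot <- NULL
  if (n_boot > 0) {
    boot <- matrix(NA_real_, n_boot, length(free),
                   dimnames = list(NULL, free))
    reps <- unique(clone_table$replicate)
    for (b in seq_len(n_boot)) {
      take <- sample(reps, length(reps), replace = TRUE)
      tab_b <- do.call(rbind, lapply(take, function(rr)
        clone_table[clone_table$replicate == rr, , drop = FALSE]))
      fb <- tryCatch(
        optim(best$par, function(th) {
          p <- fixed
          p[free] <- as.list(10^th)
          -clone_loglikelihood(p, design, tab_b)
        }, method = "L-BFGS-B", lower = lo, upper = hi,
        control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(fb)) boot[b, ] <- 10^fb$par
    }
  }

  structure(list(estimates = est, logLik = -best$value, starts = starts_tab,
                 fixed = fixed, free = free, bounds = bounds,
                 convergence = best$convergence, boot = boot, seed = seed),
            class = "crispr_fit")
}

#' @export
coef.crispr_fit <- function(object, ...) object$estimates

#' @export
logLik.crispr_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$free), class = "logLik")
}

#' @export
print.crispr_fit <- function(x, ...) {
  cat("Multinomial maximum-likelihood fit (crispr_fit)\n")
  if (length(x$free)) {
    cat("Free parameters:\n")
    for (nm in x$free)
      cat(sprintf("  %-4s = %.4g  (bounds [%g, %g])\n", nm,
                  x$estimates[[nm]], x$bounds[[nm]][1], x$bounds[[nm]][2]))
  } else cat("Evaluation mode (no free parameters)\n")
  cat(sprintf("log-likelihood: %.4f\n", x$logLik))
  invisible(x)
}

#' @export
summary.crispr_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$starts)) {
    cat(sprintf("Starts: %d (%d converged); best re-found by %d\n",
                nrow(object$starts), sum(object$starts$converged),
                sum(abs(object$starts$logLik - object$logLik) < 1e-6)))
  }
  if (!is.null(object$boot)) {
    cat("Bootstrap percentile intervals (2.5%, 97.5%):\n")
    for (nm in object$free) {
      qs <- stats::quantile(object$boot[, nm], c(0.025, 0.975), na.rm = TRUE)
      cat(sprintf("  %-4s: [%.4g, %.4g]\n", nm, qs[1], qs[2]))
    }
  }
  invisible(object)
}

#' Simulate new clone tables from a fitted model
#'
#' @param object a `crispr_fit`.
#' @param nsim number of datasets.
#' @param seed base seed (dataset `i` uses `seed + i`).
#' @param design the design to simulate under (default: refit design not
#'   stored; must be supplied).
#' @param ... passed to [generate_dataset()].
#' @return A list of `synthetic_dataset`s (length `nsim`).
#' @export
simulate.crispr_fit <- function(object, nsim = 1, seed = 1, design, ...) {
  p <- object$fixed
  p[object$free] <- as.list(object$estimates)
  lapply(seq_len(nsim), function(i)
    generate_dataset(design, p, seed = seed + i, ...))
}
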