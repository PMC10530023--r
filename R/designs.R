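#' Factorial experiment designs
#'
#' An `experiment_design` is a table of treatments (initial phage dose `V0`,
#' carrying capacity `K`, inoculum fraction of sensitive cells relative to
#' `K`), a serial-transfer protocol, the sampling days and a replicate
#' count. Sampling days are the transfer boundaries (end of each 20 h batch,
#' pre-dilution), mirroring daily plating.
#'
#' @param treatments data.frame with columns `V0`, `K`, `inoculum_fraction`
#'   (and optionally `treatment`, a label; one is generated otherwise).
#' @param protocol a [transfer_protocol()].
#' @param sampling_days integer days (1 = end of first batch).
#' @param n_replicates replicate count used by the synthetic-data sampler.
#' @param label design label.
#' @return An object of class `experiment_design`.
#' @seealso [bundled_design()] for the designs used throughout.
#' @export
experiment_design <- function(treatments, protocol = transfer_protocol(),
                              sampling_days = seq_len(protocol$n_transfers),
                              n_replicates = 6, label = "custom") {
  if (!is.data.frame(treatments) || nrow(treatments) == 0)
    stop("experiment_design: empty design", call. = FALSE)
  need <- c("V0", "K", "inoculum_fraction")
  miss <- setdiff(need, names(treatments))
  if (length(miss))
    stop("experiment_design: treatments lack column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(treatments$inoculum_fraction <= 0 |
          treatments$inoculum_fraction > 1))
    stop("experiment_design: inoculum_fraction must be in (0, 1]",
         call. = FALSE)
  if (any(treatments$V0 < 0) || any(treatments$K <= 0))
    stop("experiment_design: V0 >= 0 and K > 0 required", call. = FALSE)
  if (any(sampling_days < 1 | sampling_days > protocol$n_transfers))
    stop("experiment_design: sampling_days outside the protocol",
         call. = FALSE)
  if (is.null(treatments$treatment))
    treatments$treatment <- sprintf("V0=%.3g|K=%.3g|S0=%.3gK",
                                    treatments$V0, treatments$K,
                                    treatments$inoculum_fraction)
  structure(list(treatments = treatments, protocol = protocol,
                 sampling_days = as.integer(sort(unique(sampling_days))),
                 n_replicates = as.integer(n_replicates), label = label),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment design '%s': %d treatments, %d replicates, days %s\n",
              x$label, nrow(x$treatments), x$n_replicates,
              paste(x$sampling_days, collapse = ",")))
  print(x$protocol)
  print(utils::head(x$treatments, 8), row.names = FALSE)
  if (nrow(x$treatments) > 8) cat("...\n")
  invisible(x)
}

#' Bundled experiment designs
#'
#' The designs used in the simulation study:
#' \describe{
#'   \item{`"inoculum_sweep"`}{inoculum fractions S0/K of 0.1, 0.01, 0.001,
#'     0.0001 at fixed phage dose V0 = 1e6 and K = 1e8, one 20 h batch
#'     (model counterpart of the 10%-to-0.01% inoculum experiment).}
#'   \item{`"moi_matched_sweep"`}{same inoculum fractions but V0 scaled to
#'     keep the initial MOI at 0.1.}
#'   \item{`"dose_capacity_grid"`}{full factorial V0 in {1e2, 1e4, 1e6, 1e8,
#'     1e10} by K in {1e6, 1e7, 1e8, 1e9}, 3 daily transfers, start at
#'     K/100. The top dose reaches the regime where infection-induced
#'     toxicity makes surface resistance, not CRISPR, the winning defence.}
#'   \item{`"fig3_analogue"`}{factorial V0 in {1e1, 1e3, 1e5, 1e9} by the
#'     same K levels, 3 daily transfers, 6 replicates, 24-clone typing
#'     (dose-by-glucose experiment counterpart).}
#'   \item{`"s4_defaults"`}{single treatment V0 = 1e4, K = 1e8, S0 = K/100,
#'     3 daily transfers (the transient-dynamics / LD setup).}
#' }
#' The K levels stand in for the four glucose concentrations
#' (0.0002-0.2%), spanning 1e6-1e9 cells/ml; 1e8 is the default media.
#'
#' @param name design name.
#' @return An [experiment_design()].
#' @examples
#' bundled_design("inoculum_sweep")
#' @export
bundled_design <- function(name = c("inoculum_sweep", "moi_matched_sweep",
                                    "dose_capacity_grid", "fig3_analogue",
                                    "s4_defaults")) {
  name <- match.arg(name)
  K_levels <- c(1e6, 1e7, 1e8, 1e9)
  switch(name,
    inoculum_sweep = {
      fr <- c(1e-4, 1e-3, 1e-2, 1e-1)
      experiment_design(
        data.frame(V0 = 1e6, K = 1e8, inoculum_fraction = fr),
        protocol = transfer_protocol(n_transfers = 1),
        sampling_days = 1, label = name)
    },
    moi_matched_sweep = {
      fr <- c(1e-4, 1e-3, 1e-2, 1e-1)
      experiment_design(
        data.frame(V0 = 0.1 * fr * 1e8, K = 1e8, inoculum_fraction = fr),
        protocol = transfer_protocol(n_transfers = 1),
        sampling_days = 1, label = name)
    },
    dose_capacity_grid = {
      gr <- expand.grid(V0 = c(1e2, 1e4, 1e6, 1e8, 1e10), K = K_levels)
      gr$inoculum_fraction <- 0.01
      experiment_design(gr, label = name)
    },
    fig3_analogue = {
      gr <- expand.grid(V0 = c(1e1, 1e3, 1e5, 1e9), K = K_levels)
      gr$inoculum_fraction <- 0.01
      experiment_design(gr, label = name)
    },
    s4_defaults = experiment_design(
      data.frame(V0 = 1e4, K = 1e8, inoculum_fraction = 0.01),
      label = name)
  )
}

#' Run every treatment of a design through the deterministic model
#'
#' Integrates each treatment (initial state `S = inoculum_fraction * K`,
#' free phage `V0`, all resistant classes 0) through the design's protocol
#' and reports densities and genotype frequencies at each sampling day
#' (end-of-batch, pre-dilution). Deterministic: replicates only differ
#' after synthetic sampling.
#'
#' @param design an [experiment_design()].
#' @param params a [model_params()]; its `K` is overridden per treatment.
#' @param control a [solver_options()].
#' @return A data.frame with one row per treatment x sampling day:
#'   treatment label, `V0`, `K`, `inoculum_fraction`, `day`, `t`, densities
#'   `S R C D V`, total `N`, frequencies `f_S f_R f_C f_D`, and `LD`.
#' @examples
#' head(run_design_grid(bundled_design("inoculum_sweep"), model_params()))
#' @export
run_design_grid <- function(design, params = model_params(),
                            control = solver_options()) {
  stopifnot(inherits(design, "experiment_design"))
  tr <- design$treatments
  out <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    p_i <- params
    p_i$K <- tr$K[i]
    s0 <- pop_state(S = tr$inoculum_fraction[i] * tr$K[i], V = tr$V0[i])
    traj <- run_protocol(s0, p_i, design$protocol, control = control)
    idx <- traj$boundaries[design$sampling_days]
    st <- traj$states[idx, , drop = FALSE]
    N <- rowSums(st[, c("S", "R", "C", "D"), drop = FALSE])
    f <- st[, c("S", "R", "C", "D"), drop = FALSE] / N
    colnames(f) <- c("f_S", "f_R", "f_C", "f_D")
    out[[i]] <- data.frame(
      treatment = tr$treatment[i], V0 = tr$V0[i], K = tr$K[i],
      inoculum_fraction = tr$inoculum_fraction[i],
      day = design$sampling_days, t = traj$times[idx],
      st, N = N, f,
      LD = f[, "f_S"] * f[, "f_D"] - f[, "f_R"] * f[, "f_C"],
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "design_label") <- design$label
  res
}
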