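#' Time-derivatives of the five-compartment system with a flux breakdown
#'
#' Computes `d(S,R,C,D,V)/dt` at a given state, together with the individual
#' nonnegative fluxes that compose them. With `g = 1 - N/K` the default
#' configuration is
#' \deqn{dS = r_S g S - aVS - M(S) - AaVS + LC - mS}
#' \deqn{dR = r_R g R + M(S) + LD - mR}
#' \deqn{dC = r_C g C + AaVS - M(C) - LC - mC}
#' \deqn{dD = r_D g D + M(C) - LD - mD}
#' \deqn{dV = BaVS - aV(S + C) - m_v V}
#' where the mutation flux is `M(X) = mu * r_X * g * X` under the
#' per-replication model (default) or `mu * X` per capita. Structural
#' switches on [model_params()] add spacer acquisition from R and/or make
#' acquisition subtract from the lysis flux. Adsorption to R and D removes
#' no phage; adsorption to C removes phage without a burst (phage sink).
#'
#' @param state a [pop_state()] (nonnegative densities).
#' @param params a [model_params()].
#' @return A list with `derivatives` (named vector, per hour) and
#'   `breakdown`, a named vector of nonnegative fluxes such that each
#'   derivative is exactly the signed sum of its fluxes (see
#'   [flux_balance()]).
#' @examples
#' d <- model_derivatives(pop_state(S = 1e6, V = 1e4), model_params())
#' d$derivatives
#' @export
model_derivatives <- function(state, params) {
  stopifnot(inherits(params, "model_params"))
  state <- as_pop_state(state, t = attr(state, "t") %||% 0)
  x <- unclass(state)
  S <- x[["S"]]; R <- x[["R"]]; C <- x[["C"]]; D <- x[["D"]]; V <- x[["V"]]
  N <- S + R + C + D
  g <- 1 - N / params$K
  gr <- genotype_growth_rates(params, V)

  M_S <- if (params$mutation_model == "per_replication")
    params$mu * gr[["r_S"]] * g * S else params$mu * S
  M_C <- if (params$mutation_model == "per_replication")
    params$mu * gr[["r_C"]] * g * C else params$mu * C

  adsS <- params$a * V * S
  lysS <- if (params$rescue_on_acquisition) (1 - params$A) * adsS else adsS
  acqS <- params$A * params$a * V * S
  acqR <- if (params$acquisition_from_R) params$A * params$a * V * R else 0

  fl <- c(growth_S = gr[["r_S"]] * g * S,
          growth_R = gr[["r_R"]] * g * R,
          growth_C = gr[["r_C"]] * g * C,
          growth_D = gr[["r_D"]] * g * D,
          lysis_S = lysS,
          acquisition_S = acqS,
          acquisition_R = acqR,
          mutation_S = M_S,
          mutation_C = M_C,
          loss_C = params$L * C,
          loss_D = params$L * D,
          death_S = params$m * S,
          death_R = params$m * R,
          death_C = params$m * C,
          death_D = params$m * D,
          phage_production = params$B * lysS,
          phage_adsorption_S = adsS,
          phage_adsorption_C = params$a * V * C,
          phage_decay = params$m_v * V)

  list(derivatives = flux_balance(fl), breakdown = fl)
}

#' Reassemble compartment derivatives from a flux breakdown
#'
#' Bookkeeping identity: each compartment derivative is the signed sum of
#' the named fluxes entering and leaving it. Used as a property test of
#' [model_derivatives()].
#'
#' @param fl a flux breakdown as returned in
#'   `model_derivatives()$breakdown`.
#' @return Named derivative vector `c(S, R, C, D, V)`.
#' @export
flux_balance <- function(fl) {
  c(S = fl[["growth_S"]] - fl[["lysis_S"]] - fl[["mutation_S"]] -
        fl[["acquisition_S"]] + fl[["loss_C"]] - fl[["death_S"]],
    R = fl[["growth_R"]] + fl[["mutation_S"]] + fl[["loss_D"]] -
        fl[["acquisition_R"]] - fl[["death_R"]],
    C = fl[["growth_C"]] + fl[["acquisition_S"]] - fl[["mutation_C"]] -
        fl[["loss_C"]] - fl[["death_C"]],
    D = fl[["growth_D"]] + fl[["mutation_C"]] + fl[["acquisition_R"]] -
        fl[["loss_D"]] - fl[["death_D"]],
    V = fl[["phage_production"]] - fl[["phage_adsorption_S"]] -
        fl[["phage_adsorption_C"]] - fl[["phage_decay"]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
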