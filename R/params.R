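#' Model parameters
#'
#' Constructs and validates the rate constants and structural switches of the
#' eco-evolutionary model. The defaults are the published simulation
#' parameter set: maximal growth rate `r` of 1 per hour, no background host or
#' phage mortality, adsorption constant `a = 1e-8` ml/phage/h, burst size
#' `B = 100`, constitutive cost of surface resistance `c_R = 0.01` (entering
#' as `exp(-c_R)`), infection-induced CRISPR toxicity `tau = 0.01` (entering
#' as `exp(-tau*a*V)`), surface-mutation rate `mu = 1e-4`, spacer-acquisition
#' efficiency `A = 5e-4` (multiplying the adsorption rate `a*V`), CRISPR-loss
#' rate `L = 1e-3` per hour, and carrying capacity `K = 1e8` cells/ml.
#'
#' @param r maximal per-capita host growth rate (per hour); sensitive hosts
#'   grow at `r`, surface mutants and double mutants at `exp(-c_R)*r`,
#'   CRISPR-immune hosts at `exp(-tau*a*V)*r`.
#' @param m host background mortality rate (per hour).
#' @param m_v free-phage decay rate (per hour).
#' @param a adsorption rate constant (ml per phage per hour).
#' @param B burst size: phage released per lysed cell (>= 1).
#' @param c_R constitutive cost of surface resistance (dimensionless).
#' @param tau infection-induced toxicity of CRISPR immunity (dimensionless).
#' @param mu surface-mutation rate. Under the default `per_replication`
#'   mutation model this is a probability per replication (mutant flux
#'   `mu * r_X * g * X`); under `per_capita` it is a rate per cell per hour.
#' @param A spacer-acquisition efficiency: sensitive cells acquire CRISPR
#'   immunity at rate `A * a * V`.
#' @param L resistance-loss rate (per hour): CRISPR immunity is lost as
#'   C -> S and D -> R.
#' @param K carrying capacity (cells per ml); growth is multiplied by the
#'   logistic factor `g = 1 - N/K`.
#' @param mutation_model `"per_replication"` (default; receptor mutation is
#'   tied to replication) or `"per_capita"` (constant per-cell rate).
#' @param acquisition_from_R can surface mutants also acquire spacers
#'   (R -> D at `A*a*V`)? Default `FALSE`: surface modification blocks
#'   adsorption, hence exposure.
#' @param rescue_on_acquisition if `TRUE`, spacer acquisition subtracts from
#'   the lysis flux (lysis becomes `(1-A)*a*V*S`). Default `FALSE`.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params()           # published defaults
#' p2 <- model_params(tau = 0)   # no CRISPR toxicity
#' @export
model_params <- function(r = 1, m = 0, m_v = 0, a = 1e-8, B = 100,
                         c_R = 0.01, tau = 0.01, mu = 1e-4, A = 5e-4,
                         L = 1e-3, K = 1e8,
                         mutation_model = c("per_replication", "per_capita"),
                         acquisition_from_R = FALSE,
                         rescue_on_acquisition = FALSE) {
  mutation_model <- match.arg(mutation_model)
  p <- list(r = r, m = m, m_v = m_v, a = a, B = B, c_R = c_R, tau = tau,
            mu = mu, A = A, L = L, K = K,
            mutation_model = mutation_model,
            acquisition_from_R = isTRUE(acquisition_from_R),
            rescue_on_acquisition = isTRUE(rescue_on_acquisition))
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  num <- c("r", "m", "m_v", "a", "B", "c_R", "tau", "mu", "A", "L", "K")
  vals <- unlist(p[num])
  if (any(!is.finite(vals)))
    stop("model_params: non-finite value for ", paste(num[!is.finite(vals)],
         collapse = ", "), call. = FALSE)
  if (any(vals < 0))
    stop("model_params: negative value for ",
         paste(num[vals < 0], collapse = ", "), call. = FALSE)
  if (p$B < 1) stop("model_params: burst size B must be >= 1", call. = FALSE)
  if (p$K <= 0) stop("model_params: K must be > 0", call. = FALSE)
  invisible(p)
}

# C++ interface: parameter and switch vectors (order fixed by src/model.h)
param_vector <- function(p) {
  c(p$r, p$m, p$m_v, p$a, p$B, p$c_R, p$tau, p$mu, p$A, p$L, p$K)
}

switch_vector <- function(p) {
  as.integer(c(p$mutation_model == "per_capita",
               p$acquisition_from_R, p$rescue_on_acquisition))
}

#' @export
print.model_params <- function(x, ...) {
  cat("Eco-evolutionary model parameters\n")
  num <- c("r", "m", "m_v", "a", "B", "c_R", "tau", "mu", "A", "L", "K")
  cat(paste0("  ", format(num, width = 4), " = ",
             vapply(x[num], format, "", digits = 6)), sep = "\n")
  cat("  mutation model:      ", x$mutation_model, "\n")
  cat("  acquisition from R:  ", x$acquisition_from_R, "\n")
  cat("  rescue on acquisition:", x$rescue_on_acquisition, "\n")
  invisible(x)
}

#' Population state
#'
#' A snapshot of the five compartments: sensitive cells `S`, surface mutants
#' `R`, CRISPR-immune cells `C`, double-resistant cells `D` (densities in
#' cells/ml) and free phage `V` (phage/ml), at time `t` (hours).
#'
#' @param S,R,C,D,V nonnegative densities.
#' @param t time in hours.
#' @return A named numeric vector of class `pop_state` with a `t` attribute.
#' @examples
#' pop_state(S = 1e6, V = 1e4)
#' @export
pop_state <- function(S = 0, R = 0, C = 0, D = 0, V = 0, t = 0) {
  x <- c(S = S, R = R, C = C, D = D, V = V)
  if (any(!is.finite(x))) stop("pop_state: non-finite density", call. = FALSE)
  if (any(x < 0)) stop("pop_state: negative density", call. = FALSE)
  structure(x, t = t, class = "pop_state")
}

as_pop_state <- function(x, t = 0) {
  if (inherits(x, "pop_state")) return(x)
  pop_state(x[["S"]], x[["R"]], x[["C"]], x[["D"]], x[["V"]], t = t)
}

#' @export
print.pop_state <- function(x, ...) {
  cat(sprintf("Population state at t = %g h\n", attr(x, "t")))
  print(setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Total host density
#' @param state a [pop_state()].
#' @return `S + R + C + D`.
#' @export
total_hosts <- function(state) {
  sum(unclass(state)[c("S", "R", "C", "D")])
}

#' Per-capita intrinsic growth rates of the four host genotypes
#'
#' Before density dependence, sensitive hosts grow at `r_S = r`, surface
#' mutants and double mutants pay the constitutive cost (`r_R = r_D =
#' exp(-c_R) * r`) and CRISPR-immune hosts pay the infection-induced
#' toxicity cost (`r_C = exp(-tau*a*V) * r`), which vanishes without phage.
#'
#' @param params a [model_params()] object.
#' @param V free-phage density (phage/ml), `>= 0`.
#' @return Named vector `c(r_S, r_R, r_C, r_D)`.
#' @examples
#' genotype_growth_rates(model_params(), V = 1e8)
#' @export
genotype_growth_rates <- function(params, V) {
  stopifnot(inherits(params, "model_params"))
  if (!is.finite(V) || V < 0)
    stop("genotype_growth_rates: V must be finite and >= 0", call. = FALSE)
  r_R <- exp(-params$c_R) * params$r
  c(r_S = params$r, r_R = r_R,
    r_C = exp(-params$tau * params$a * V) * params$r, r_D = r_R)
}
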