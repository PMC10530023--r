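#' Genotype frequencies among hosts
#'
#' @param state a [pop_state()] with total host density `N > 0`.
#' @return Named vector `c(f_S, f_R, f_C, f_D)` summing to 1.
#' @examples
#' genotype_frequencies(pop_state(S = 2.5e7, R = 2.5e7, C = 2.5e7, D = 2.5e7))
#' @export
genotype_frequencies <- function(state) {
  x <- unclass(as_pop_state(state, attr(state, "t") %||% 0))
  N <- sum(x[c("S", "R", "C", "D")])
  if (N <= 0)
    stop("genotype_frequencies: undefined, total host density is 0",
         call. = FALSE)
  setNames(x[c("S", "R", "C", "D")] / N, c("f_S", "f_R", "f_C", "f_D"))
}

#' Two-locus linkage disequilibrium between the resistance loci
#'
#' `LD = f_S * f_D - f_R * f_C`. Negative LD means single-resistance
#' haplotypes (R-only, C-only) are over-represented relative to random
#' association of the two loci -- the footprint of the strong negative
#' epistasis between the two defences (double resistance protects no better
#' than single resistance but still pays the constitutive cost).
#'
#' @param freqs frequencies from [genotype_frequencies()], or a
#'   [pop_state()].
#' @return Scalar LD.
#' @examples
#' linkage_disequilibrium(c(f_S = 0.4, f_R = 0.3, f_C = 0.2, f_D = 0.1))
#' @export
linkage_disequilibrium <- function(freqs) {
  if (inherits(freqs, "pop_state")) freqs <- genotype_frequencies(freqs)
  freqs[["f_S"]] * freqs[["f_D"]] - freqs[["f_R"]] * freqs[["f_C"]]
}

#' Per-allele selection coefficients
#'
#' The selection coefficient of an allele is the difference between the
#' abundance-weighted per-capita net growth rate of its carriers and that of
#' the non-carriers: carriers are {R, D} for the surface-resistance allele
#' and {C, D} for the CRISPR allele. Net growth counts births (`r_X * g`)
#' and deaths (lysis of S, background mortality) but deliberately excludes
#' the mutation, acquisition and loss fluxes, so it measures selection
#' rather than mutant supply; in the limit `mu -> 0, A -> 0, L = 0` it
#' equals `d/dt logit(f_carriers)`.
#'
#' Each coefficient is decomposed into a growth-differential component
#' (cost of resistance, toxicity) and a phage-protection component (escape
#' from lysis); the two sum to the total.
#'
#' @param state a [pop_state()]. A coefficient requires carriers and
#'   non-carriers of its focal allele both present; it is `NA` otherwise,
#'   and an error is raised when both coefficients are undefined.
#' @param params a [model_params()].
#' @return Object of class `selection_report`: list with `time`, `s_R`,
#'   `s_C` (per hour) and `components`, each `c(growth, phage)`.
#' @examples
#' st <- pop_state(S = 2.5e7, R = 2.5e7, C = 1e5, D = 10, V = 1e6)
#' selection_coefficients(st, model_params())
#' @export
selection_coefficients <- function(state, params) {
  comp <- sel_components(state, params)
  if (anyNA(comp$s_R) && anyNA(comp$s_C))
    stop("selection_coefficients: carriers or non-carriers absent for ",
         "both alleles, coefficients undefined", call. = FALSE)
  structure(list(time = attr(as_pop_state(state, attr(state, "t") %||% 0),
                             "t"),
                 s_R = sum(comp$s_R), s_C = sum(comp$s_C),
                 components = comp),
            class = "selection_report")
}

# components of both selection coefficients; NA when carriers or
# non-carriers of the focal allele are absent
sel_components <- function(state, params) {
  stopifnot(inherits(params, "model_params"))
  state <- as_pop_state(state, attr(state, "t") %||% 0)
  x <- unclass(state)
  N <- sum(x[c("S", "R", "C", "D")])
  g <- 1 - N / params$K
  gr <- genotype_growth_rates(params, x[["V"]])
  lys <- (if (params$rescue_on_acquisition) 1 - params$A else 1) *
    params$a * x[["V"]]
  # per-capita net growth (births - deaths), supply fluxes excluded
  w <- c(S = gr[["r_S"]] * g - lys - params$m,
         R = gr[["r_R"]] * g - params$m,
         C = gr[["r_C"]] * g - params$m,
         D = gr[["r_D"]] * g - params$m)
  wg <- c(S = gr[["r_S"]] * g - params$m, R = gr[["r_R"]] * g - params$m,
          C = gr[["r_C"]] * g - params$m, D = gr[["r_D"]] * g - params$m)
  one_allele <- function(car, non) {
    nc <- sum(x[car]); nn <- sum(x[non])
    if (nc <= 0 || nn <= 0) return(c(growth = NA_real_, phage = NA_real_))
    tot <- sum(x[car] * w[car]) / nc - sum(x[non] * w[non]) / nn
    growth <- sum(x[car] * wg[car]) / nc - sum(x[non] * wg[non]) / nn
    c(growth = growth, phage = tot - growth)
  }
  list(s_R = one_allele(c("R", "D"), c("S", "C")),
       s_C = one_allele(c("C", "D"), c("S", "R")))
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Selection coefficients at t = %g h (per hour)\n", x$time))
  cat(sprintf("  s_R = %+.6g  (growth %+.3g, phage %+.3g)\n", x$s_R,
              x$components$s_R[["growth"]], x$components$s_R[["phage"]]))
  cat(sprintf("  s_C = %+.6g  (growth %+.3g, phage %+.3g)\n", x$s_C,
              x$components$s_C[["growth"]], x$components$s_C[["phage"]]))
  invisible(x)
}

#' Population-genetic metrics along a trajectory
#'
#' Frequencies, linkage disequilibrium and (where defined) selection
#' coefficients at every sampled time of a trajectory.
#'
#' @param traj a `trajectory` from [run_protocol()] or [integrate_batch()].
#' @param params a [model_params()]; defaults to the trajectory's.
#' @return data.frame with columns `t`, `f_S..f_D`, `LD`, `s_R`, `s_C`
#'   (NA where an allele class is absent).
#' @export
selection_trajectory <- function(traj, params = traj$params) {
  st <- traj$states
  n <- nrow(st)
  f <- matrix(NA_real_, n, 4,
              dimnames = list(NULL, c("f_S", "f_R", "f_C", "f_D")))
  sR <- sC <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    N <- sum(st[i, c("S", "R", "C", "D")])
    if (N <= 0) next
    f[i, ] <- st[i, c("S", "R", "C", "D")] / N
    comp <- sel_components(as_pop_state(st[i, ], t = traj$times[i]), params)
    sR[i] <- sum(comp$s_R)
    sC[i] <- sum(comp$s_C)
  }
  ld <- f[, "f_S"] * f[, "f_D"] - f[, "f_R"] * f[, "f_C"]
  data.frame(t = traj$times, f, LD = ld, s_R = sR, s_C = sC)
}

#' Time-integrated selection and interference with the surface allele
#'
#' Reruns the default transient setup (or `base_design`) for each
#' spacer-acquisition efficiency in `acquisition_values` and reports the
#' time-integral of the surface-allele selection coefficient
#' (trapezoid rule over solver output times, from the first time both
#' allele classes exist) and the final surface-mutant frequency. The faster
#' CRISPR immunity is acquired, the more it interferes with selection for
#' surface resistance: the resistant fraction rises (less benefit to spare)
#' and phage density drops (less selective pressure).
#'
#' @param base_design an [experiment_design()] with a single treatment;
#'   default the 3-transfer transient setup (V0 = 1e4, K = 1e8, S0 = K/100).
#' @param params a [model_params()].
#' @param acquisition_values positive values of `A` to sweep.
#' @param control a [solver_options()].
#' @return data.frame with columns `A`, `integrated_s_R`, `final_f_R`.
#' @examples
#' \donttest{
#' interference_curve(acquisition_values = c(5e-5, 5e-4, 5e-3))
#' }
#' @export
interference_curve <- function(base_design = bundled_design("s4_defaults"),
                               params = model_params(),
                               acquisition_values = c(5e-5, 5e-4, 5e-3),
                               control = solver_options()) {
  stopifnot(inherits(base_design, "experiment_design"),
            nrow(base_design$treatments) == 1)
  if (any(acquisition_values <= 0))
    stop("interference_curve: acquisition values must be > 0", call. = FALSE)
  tr1 <- base_design$treatments[1, ]
  out <- lapply(acquisition_values, function(Aval) {
    p <- params
    p$A <- Aval
    p$K <- tr1$K
    s0 <- pop_state(S = tr1$inoculum_fraction * tr1$K, V = tr1$V0)
    traj <- run_protocol(s0, p, base_design$protocol, control = control)
    met <- selection_trajectory(traj, p)
    ok <- !is.na(met$s_R)
    int_sR <- trapezoid(met$t[ok], met$s_R[ok])
    fin <- genotype_frequencies(final_state(traj))
    data.frame(A = Aval, integrated_s_R = int_sR,
               final_f_R = fin[["f_R"]])
  })
  do.call(rbind, out)
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(NA_real_)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}
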