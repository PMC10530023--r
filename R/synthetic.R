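#' Two-phage streak assay: phenotype from assay result
#'
#' Clones are streaked against the plain phage and against the same phage
#' carrying an anti-CRISPR (Acr), which disables CRISPR immunity but not
#' surface-based resistance. Sensitive clones are susceptible to both,
#' surface mutants (sm) are resistant to both, and CRISPR clones are
#' resistant to the plain phage only.
#'
#' @param resistant_to_phage logical: clone resists the plain phage.
#' @param resistant_to_acr_phage logical: clone resists the Acr-carrying
#'   phage.
#' @return Character vector in `{"sensitive", "sm", "crispr"}` (vectorised).
#' @examples
#' classify_phenotype(c(FALSE, TRUE, TRUE), c(FALSE, TRUE, FALSE))
#' @export
classify_phenotype <- function(resistant_to_phage, resistant_to_acr_phage) {
  stopifnot(is.logical(resistant_to_phage),
            is.logical(resistant_to_acr_phage),
            length(resistant_to_phage) == length(resistant_to_acr_phage))
  bad <- !resistant_to_phage & resistant_to_acr_phage
  if (any(bad))
    stop("classify_phenotype: inconsistent assay (resistant to the ",
         "Acr-phage but not the plain phage) at position ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  ifelse(!resistant_to_phage, "sensitive",
         ifelse(resistant_to_acr_phage, "sm", "crispr"))
}

#' Expected streak-assay result for each genotype
#'
#' Sensitive cells (S) resist neither phage; surface mutants (R) resist
#' both (no adsorption); CRISPR-immune cells (C) resist the plain phage but
#' not the Acr-carrying one. Double mutants (D) resist both: the Acr only
#' disables CRISPR while the receptor mutation still blocks adsorption, so
#' D clones score as sm -- the observed "sm fraction" therefore estimates
#' `f_R + f_D`.
#'
#' @param genotype character vector in `{"S", "R", "C", "D"}`.
#' @return data.frame with logical columns `resistant_to_phage` and
#'   `resistant_to_acr_phage`.
#' @examples
#' genotype_to_assay(c("S", "R", "C", "D"))
#' @export
genotype_to_assay <- function(genotype) {
  if (!all(genotype %in% c("S", "R", "C", "D")))
    stop("genotype_to_assay: genotype must be one of S, R, C, D",
         call. = FALSE)
  data.frame(
    resistant_to_phage = genotype != "S",
    resistant_to_acr_phage = genotype %in% c("R", "D"))
}

#' Sample synthetic clone-typing tables from deterministic truths
#'
#' For every treatment x day row of a design-grid result and every
#' replicate, draws `n_clones` clones whose assay classes follow a
#' multinomial over (sensitive, sm, crispr) with probabilities
#' `(f_S, f_R + f_D, f_C)` -- double mutants score as sm in the streak
#' assay. With `overdispersion > 0`, the class probabilities are first
#' drawn per replicate from a Dirichlet with correlation parameter `rho`
#' (`alpha = p * (1 - rho) / rho`), inflating the across-replicate
#' variance.
#'
#' @param truth data.frame from [run_design_grid()] (columns `treatment`,
#'   `day`, `f_S`, `f_R`, `f_C`, `f_D`).
#' @param n_clones clones typed per replicate (default 24).
#' @param n_replicates replicates per treatment (default 6).
#' @param seed integer seed.
#' @param overdispersion rho in \[0, 1).
#' @return A data.frame of class `clone_table`: one row per treatment x
#'   replicate x day with counts `n_sensitive`, `n_sm`, `n_crispr` summing
#'   to `n_clones`; generator metadata in attributes.
#' @examples
#' truth <- run_design_grid(bundled_design("inoculum_sweep"), model_params())
#' ct <- sample_clone_table(truth, seed = 42)
#' head(ct)
#' @export
sample_clone_table <- function(truth, n_clones = 24, n_replicates = 6,
                               seed = 1, overdispersion = 0) {
  if (n_clones <= 0)
    stop("sample_clone_table: n_clones must be positive", call. = FALSE)
  if (overdispersion < 0 || overdispersion >= 1)
    stop("sample_clone_table: overdispersion must be in [0, 1)",
         call. = FALSE)
  need <- c("treatment", "day", "f_S", "f_R", "f_C", "f_D")
  if (!all(need %in% names(truth)))
    stop("sample_clone_table: truth lacks columns ",
         paste(setdiff(need, names(truth)), collapse = ", "), call. = FALSE)
  set.seed(seed)
  rows <- vector("list", nrow(truth) * n_replicates)
  k <- 0
  for (i in seq_len(nrow(truth))) {
    p0 <- c(truth$f_S[i], truth$f_R[i] + truth$f_D[i], truth$f_C[i])
    p0 <- pmax(p0, 0)
    p0 <- p0 / sum(p0)
    for (rep in seq_len(n_replicates)) {
      p <- if (overdispersion > 0) rdirichlet_compound(p0, overdispersion)
           else p0
      cnt <- as.vector(rmultinom(1, n_clones, p))
      k <- k + 1
      rows[[k]] <- data.frame(treatment = truth$treatment[i],
                              replicate = rep, day = truth$day[i],
                              n_sensitive = cnt[1], n_sm = cnt[2],
                              n_crispr = cnt[3])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_clones") <- n_clones
  attr(out, "seed") <- seed
  attr(out, "overdispersion") <- overdispersion
  class(out) <- c("clone_table", "data.frame")
  out
}

# Dirichlet draw with mean p and correlation parameter rho
rdirichlet_compound <- function(p, rho) {
  alpha <- p * (1 - rho) / rho
  x <- vapply(alpha, function(a) if (a > 0) rgamma(1, a) else 0, numeric(1))
  if (sum(x) == 0) return(p)
  x / sum(x)
}

#' Generate a full synthetic dataset (clone tables + plate counts)
#'
#' Runs the deterministic model over a design, then emulates the study's
#' observations: per-replicate 24-clone streak-assay tables (multinomial,
#' optionally Dirichlet-overdispersed) and per-replicate CFU/PFU counts
#' with multiplicative lognormal plating noise of coefficient of variation
#' `count_cv` (mean-one multiplier; `count_cv = 0` returns the exact
#' deterministic truth).
#'
#' @param design an [experiment_design()].
#' @param params a [model_params()].
#' @param noise list with `count_cv` (default 0.2) and `overdispersion`
#'   (default 0).
#' @param seed integer seed; clone sampling uses `seed`, count noise
#'   `seed + 1`.
#' @param control a [solver_options()].
#' @return List of class `synthetic_dataset`: `clones` (a `clone_table`),
#'   `counts` (treatment, replicate, day, cfu_per_ml, pfu_per_ml), `truth`
#'   (the deterministic grid) and `manifest` (seed, noise, design label,
#'   config hash).
#' @examples
#' ds <- generate_dataset(bundled_design("inoculum_sweep"), model_params(),
#'                        seed = 7)
#' head(ds$clones)
#' @export
generate_dataset <- function(design, params = model_params(),
                             noise = list(count_cv = 0.2,
                                          overdispersion = 0),
                             seed = 1, control = solver_options()) {
  noise <- modifyList(list(count_cv = 0.2, overdispersion = 0), noise)
  truth <- run_design_grid(design, params, control = control)
  clones <- sample_clone_table(truth, n_clones = 24,
                               n_replicates = design$n_replicates,
                               seed = seed,
                               overdispersion = noise$overdispersion)
  set.seed(seed + 1)
  n_rep <- design$n_replicates
  idx <- rep(seq_len(nrow(truth)), each = n_rep)
  cv <- noise$count_cv
  mult <- function(n) {
    if (cv == 0) return(rep(1, n))
    sig <- sqrt(log(1 + cv^2))
    exp(rnorm(n, -sig^2 / 2, sig))
  }
  counts <- data.frame(treatment = truth$treatment[idx],
                       replicate = rep(seq_len(n_rep), nrow(truth)),
                       day = truth$day[idx],
                       cfu_per_ml = truth$N[idx] * mult(length(idx)),
                       pfu_per_ml = truth$V[idx] * mult(length(idx)))
  structure(list(clones = clones, counts = counts, truth = truth,
                 manifest = list(seed = seed, noise = noise,
                                 design = design$label,
                                 params_hash = config_hash(params))),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset '%s': %d clone rows, %d count rows (seed %d)\n",
              x$manifest$design, nrow(x$clones), nrow(x$counts),
              x$manifest$seed))
  invisible(x)
}
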