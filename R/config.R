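#' Load and validate a configuration file
#'
#' Flat `key = value` format (one pair per line, `#` comments). Recognised
#' keys are the model parameters (`r, m, m_v, a, B, c_R, tau, mu, A, L, K`),
#' the structural switches (`mutation_model`, `acquisition_from_R`,
#' `rescue_on_acquisition`), protocol fields (`n_transfers`,
#' `hours_per_transfer`, `dilution`, `phage_dilution`), noise fields
#' (`count_cv`, `overdispersion`), `design` (a [bundled_design()] name),
#' `seed`, and `profile`. `profile = paper_defaults` resolves to the
#' published parameter set (the [model_params()] defaults); explicit keys
#' override the profile. Unknown keys are rejected.
#'
#' @param path config file path.
#' @return List of class `crisprdyn_config` with elements `params`
#'   ([model_params()]), `protocol` ([transfer_protocol()]), `design`
#'   (an [experiment_design()] or NULL), `noise`, `seed`, and `raw` (the
#'   normalised key-value list).
#' @examples
#' f <- tempfile()
#' writeLines(c("profile = paper_defaults", "tau = 0"), f)
#' cfg <- load_config(f)
#' cfg$params$tau
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("load_config: malformed line (expected key = value): '", ln, "'",
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }

  param_keys <- c("r", "m", "m_v", "a", "B", "c_R", "tau", "mu", "A", "L",
                  "K")
  switch_keys <- c("mutation_model", "acquisition_from_R",
                   "rescue_on_acquisition")
  proto_keys <- c("n_transfers", "hours_per_transfer", "dilution",
                  "phage_dilution")
  noise_keys <- c("count_cv", "overdispersion")
  other_keys <- c("profile", "design", "seed")
  known <- c(param_keys, switch_keys, proto_keys, noise_keys, other_keys)
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(kv$profile) && kv$profile != "paper_defaults")
    stop("load_config: unknown profile '", kv$profile, "'", call. = FALSE)

  as_num <- function(key) {
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("load_config: key '", key, "' is not numeric: ",
                       kv[[key]], call. = FALSE)
    v
  }
  as_bool <- function(key) {
    v <- toupper(kv[[key]])
    if (!v %in% c("TRUE", "FALSE", "0", "1"))
      stop("load_config: key '", key, "' is not logical: ", kv[[key]],
           call. = FALSE)
    v %in% c("TRUE", "1")
  }

  pargs <- list()
  for (key in intersect(param_keys, names(kv))) pargs[[key]] <- as_num(key)
  if ("mutation_model" %in% names(kv)) {
    if (!kv$mutation_model %in% c("per_replication", "per_capita"))
      stop("load_config: mutation_model must be per_replication or ",
           "per_capita", call. = FALSE)
    pargs$mutation_model <- kv$mutation_model
  }
  for (key in c("acquisition_from_R", "rescue_on_acquisition"))
    if (key %in% names(kv)) pargs[[key]] <- as_bool(key)
  params <- do.call(model_params, pargs)  # validates bounds

  prargs <- list()
  for (key in intersect(proto_keys, names(kv))) prargs[[key]] <- as_num(key)
  protocol <- do.call(transfer_protocol, prargs)

  noise <- list(count_cv = 0.2, overdispersion = 0)
  for (key in intersect(noise_keys, names(kv))) noise[[key]] <- as_num(key)
  if (noise$overdispersion < 0 || noise$overdispersion >= 1)
    stop("load_config: overdispersion must be in [0, 1)", call. = FALSE)

  design <- if (!is.null(kv$design)) bundled_design(kv$design) else NULL
  seed <- if (!is.null(kv$seed)) as.integer(as_num("seed")) else 1L

  structure(list(params = params, protocol = protocol, design = design,
                 noise = noise, seed = seed, raw = normalise_config(kv)),
            class = "crisprdyn_config")
}

# canonical ordering and formatting of a raw key-value list
normalise_config <- function(kv) {
  kv <- kv[order(names(kv))]
  lapply(kv, as.character)
}

#' Write a configuration back to file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, f))$raw`
#' equals `cfg$raw`.
#'
#' @param config a `crisprdyn_config` (or its `raw` list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- if (inherits(config, "crisprdyn_config")) config$raw else
    normalise_config(config)
  writeLines(paste(names(raw), "=", unlist(raw)), path)
  invisible(path)
}

#' Run manifest
#'
#' A machine-readable record sufficient to reproduce a run: the resolved
#' configuration (all parameters and switches), package version, seeds,
#' output file hashes and a timestamp. Written as JSON next to every
#' pipeline output.
#'
#' @param params a [model_params()].
#' @param seed integer seed(s).
#' @param files character vector of output files to hash (md5).
#' @param extra named list folded into the manifest.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(params, seed = NULL, files = character(0),
                         extra = list()) {
  stopifnot(inherits(params, "model_params"))
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else NULL
  c(list(package = "crisprdyn",
         version = as.character(utils::packageVersion("crisprdyn")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         params = unclass(params), params_hash = config_hash(params),
         seed = seed, file_hashes = hashes),
    extra)
}

#' @rdname run_manifest
#' @param manifest a manifest list from [run_manifest()].
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# md5 of the canonical JSON serialisation (tools::md5sum is file-based)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(unclass(x), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Write a tidy results table as CSV
#'
#' UTF-8, header row, '.' decimal, no row names.
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
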