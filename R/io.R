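#' Read / write snapshot tables
#'
#' Snapshots travel as TSV with header columns `time_min`, `ts_count`,
#' `mrna_count`, `n_cells` (per-cell rows use `n_cells = 1`). Reading
#' validates and aggregates through [snapshot_data()], so
#' `write_snapshots(read_snapshots(f))` round-trips exactly.
#'
#' @param path File path.
#' @param model,space Optional validation context (see [snapshot_data()]).
#' @return `read_snapshots()`: an aggregated snapshot tibble.
#' @export
read_snapshots <- function(path, model = NULL, space = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  snapshot_data(df, model = model, space = space)
}

#' @rdname read_snapshots
#' @param data Snapshot table.
#' @export
write_snapshots <- function(data, path) {
  data <- snapshot_data(data)
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read a model/run configuration file
#'
#' YAML schema (unknown keys are rejected):
#' ```yaml
#' n_alleles: 2            # gene copies per cell
#' M: 500                  # state-space truncation
#' parameters:             # pre-stimulus values, all model parameters
#'   k1: 0.01
#'   k0: 0.1
#'   mu0: 0.01
#'   mu1: 2
#'   delta: 0.05
#' stimulated:             # post-stimulus values (names = stimulus params)
#'   k1: 1
#' fixed: [delta]          # parameters held fixed during inference
#' mcmc:                   # optional sampler settings
#'   iters: 100000
#'   seed: 1
#' ```
#'
#' @param path Path to the YAML file.
#' @return List with `model` (a `gene_model`), `space`, `params`
#'   (a [parameter_set()]) and `mcmc` (list of sampler settings, possibly
#'   empty).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("n_alleles", "M", "parameters", "stimulated", "fixed", "mcmc")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  need <- setdiff(c("n_alleles", "M", "parameters"), names(cfg))
  if (length(need)) {
    stop("config is missing key(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  model <- two_state_model(cfg$n_alleles)
  space <- state_space(cfg$M, model)
  params <- parameter_set(
    unstimulated = unlist(cfg$parameters),
    stimulated = if (is.null(cfg$stimulated)) numeric(0)
                 else unlist(cfg$stimulated),
    fixed = if (is.null(cfg$fixed)) character(0) else unlist(cfg$fixed),
    model = model
  )
  mcmc_allowed <- c("iters", "seed", "sigma")
  mcmc <- if (is.null(cfg$mcmc)) list() else cfg$mcmc
  unknown <- setdiff(names(mcmc), mcmc_allowed)
  if (length(unknown)) {
    stop("unknown mcmc key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  list(model = model, space = space, params = params, mcmc = mcmc)
}

#' Persist / reload a fitted chain
#'
#' The chain itself goes to `<prefix>.tsv` (columns: `iteration`, one per
#' free parameter, `loglik`, `accepted`) and run provenance to
#' `<prefix>.json` (seed, proposal covariance, burn-in index, acceptance
#' rate, a hash of the model template, package version).
#'
#' @param fit A `burst_fit`.
#' @param prefix Output path prefix.
#' @return `write_chain()`: the prefix, invisibly. `read_chain()`: a list
#'   with `chain` (tibble) and `provenance` (list).
#' @export
write_chain <- function(fit, prefix) {
  stopifnot(inherits(fit, "burst_fit"))
  chain <- tibble::as_tibble(fit$thetas) |>
    dplyr::mutate(iteration = dplyr::row_number(), .before = 1) |>
    dplyr::mutate(loglik = fit$loglik, accepted = fit$accepted)
  readr::write_tsv(chain, paste0(prefix, ".tsv"))
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(fit$template, fit$model$name, fit$space$M), tf)
  prov <- list(
    seed = fit$seed,
    sigma = fit$sigma,
    burn_in = fit$burn_in,
    acceptance_rate = fit$acceptance_rate,
    model_hash = unname(tools::md5sum(tf)),
    free_parameters = colnames(fit$thetas),
    package_version = as.character(utils::packageVersion("snapburst"))
  )
  jsonlite::write_json(prov, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_chain
#' @export
read_chain <- function(prefix) {
  list(
    chain = readr::read_tsv(paste0(prefix, ".tsv"), show_col_types = FALSE),
    provenance = jsonlite::read_json(paste0(prefix, ".json"),
                                     simplifyVector = TRUE)
  )
}
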