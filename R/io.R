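#' Read and write abundance tables
#'
#' Datasets are long-format CSV with columns
#' `isotopomer,time,replicate,abundance` (times in hours by convention; the
#' package is unit-agnostic internally). Reading validates positivity and
#' grid completeness.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
load_dataset <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  validate_dataset(dat)
  tibble::as_tibble(dat)
}

#' @rdname load_dataset
#' @param data A long-format dataset.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read a mass-action model from YAML/JSON
#'
#' The document needs `initial` (named map of concentrations) and
#' `reactions` (list of `from`/`to`/`param`, optional `name`); `observed`
#' and `fluxes` (map flux name -> reaction name) are optional. Exemplar
#' names (`"decay2"`, `"pool3_mini"`) are also accepted in place of a path.
#'
#' @param path YAML or JSON file, or an exemplar name.
#' @return A `kb_model`.
#' @export
read_model_yaml <- function(path) {
  if (path %in% c("decay2", "pool3_mini")) return(exemplar_network(path))
  doc <- read_structured(path)
  if (is.null(doc$initial) || is.null(doc$reactions)) {
    stop_kb("model document needs `initial` and `reactions`", "kb_schema_error")
  }
  rxn <- dplyr::bind_rows(lapply(doc$reactions, function(r) {
    tibble::tibble(from = r$from %||% NA_character_,
                   to = r$to %||% NA_character_,
                   param = r$param,
                   name = r$name %||% NA_character_)
  }))
  if (all(is.na(rxn$name))) rxn$name <- NULL
  mass_action_network(rxn, initial = unlist(doc$initial),
                      observed = if (!is.null(doc$observed)) unlist(doc$observed),
                      fluxes = doc$fluxes)
}

#' Read a prior specification from YAML/JSON
#'
#' The document holds a `parameters` map: per log-rate-constant `mean`,
#' `sd` (or a full `cov` matrix at the top level), `lower`, `upper`.
#'
#' @param path YAML or JSON file.
#' @param model Optional `kb_model`; when given, entries are ordered to the
#'   model's parameters (all must be present).
#' @return A `kb_prior`.
#' @export
read_prior_yaml <- function(path, model = NULL) {
  doc <- read_structured(path)
  pars <- doc$parameters
  if (is.null(pars)) stop_kb("prior document needs `parameters`", "kb_schema_error")
  nms <- names(pars)
  if (!is.null(model)) {
    missing <- setdiff(model$parameters, nms)
    if (length(missing)) {
      stop_kb(paste0("prior missing parameters: ", paste(missing, collapse = ", ")),
              "kb_schema_error")
    }
    nms <- model$parameters
  }
  getf <- function(f) vapply(nms, function(nm) as.numeric(pars[[nm]][[f]]),
                             numeric(1))
  cv <- if (!is.null(doc$cov)) do.call(rbind, doc$cov)
  beta_prior(mean = stats::setNames(getf("mean"), nms),
             sd = if (is.null(cv)) getf("sd"), cov = cv,
             lower = getf("lower"), upper = getf("upper"))
}

#' Read sampler settings from YAML/JSON
#'
#' @param path YAML or JSON file with [sampler_config()] fields.
#' @return A `kb_config`.
#' @export
read_sampler_config <- function(path) {
  doc <- read_structured(path)
  do.call(sampler_config, doc[intersect(names(doc), names(formals(sampler_config)))])
}

read_structured <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Serialize and reload a fitted chain
#'
#' Writes `<prefix>_chain.csv` (one row per iteration: log rate constants,
#' error variances, joint log posterior) and `<prefix>_meta.json` (config,
#' seed, burn-in, acceptance bookkeeping, shrinkage hyperparameters).
#'
#' @param fit A `kb_fit`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_chain <- function(fit, prefix) {
  draws <- tibble::as_tibble(as.data.frame(fit$beta))
  s2 <- tibble::as_tibble(as.data.frame(fit$sigma2))
  names(s2) <- paste0("sigma2_", names(s2))
  tbl <- dplyr::bind_cols(
    tibble::tibble(iteration = seq_len(nrow(draws))), draws, s2,
    tibble::tibble(log_posterior = fit$lp))
  readr::write_csv(tbl, paste0(prefix, "_chain.csv"))
  meta <- list(
    package = "kineticbayes", version = as.character(utils::packageVersion("kineticbayes")),
    config = unclass(fit$config)[c("n_iter", "burn_in", "l0", "dr_onset",
                                   "gamma", "s_d", "epsilon", "seed")],
    burn_in = fit$burn_in,
    acceptance = fit$acceptance,
    hyper = unclass(fit$hyper),
    parameters = colnames(fit$beta),
    isotopomers = fit$data_info$isotopomers)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_chain
#' @return `read_chain()` returns a list with `draws` (tibble) and `meta`.
#' @export
read_chain <- function(prefix) {
  draws <- readr::read_csv(paste0(prefix, "_chain.csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  list(draws = draws, meta = meta)
}

# run provenance: config echo, seed, version, timestamps, input digests
write_manifest <- function(path, command, config, seed, inputs = character(0)) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(
    package = "kineticbayes",
    version = as.character(utils::packageVersion("kineticbayes")),
    command = command, seed = seed,
    config = config,
    inputs = digests,
    started = attr(config, "started") %||% format(Sys.time(), tz = "UTC"),
    finished = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
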