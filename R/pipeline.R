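#' Run configuration for the dynamic-fitting pipeline
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Unknown keys in `...` raise an error naming the key, so configuration
#' typos fail fast.
#'
#' @param out_dir directory for all artifacts.
#' @param records_dir directory with record CSV/JSON files; defaults to
#'   `file.path(out_dir, "records")` (where the `synth` command writes).
#' @param seed global integer seed; recorded in every artifact.
#' @param scenario list of [benchmark_scenario()] arguments for the `synth`
#'   command (fields `n_records`, `drift_param`, `drift_rate`, `noise_cv`).
#' @param selection list: `target_size`, `collinearity_threshold`,
#'   `dominance_ratio`.
#' @param optimizer list: `sigma0`, `popsize`, `max_evaluations`, `tol_cf`.
#' @param trend list: `horizon`, `min_fit_pct`, `modification_tol`,
#'   `range_gate_factor`, `ts_grid`, `max_order`.
#' @param validation list: `at_grid` (`"own"` or `"preceding"`).
#' @param ... must be empty; any leftover key is reported as a schema
#'   error.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, records_dir = NULL, seed = 1L,
                       scenario = list(), selection = list(),
                       optimizer = list(), trend = list(),
                       validation = list(), ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
    }
    x
  }
  cfg <- list(
    out_dir = out_dir,
    records_dir = records_dir %||% file.path(out_dir, "records"),
    seed = as.integer(seed),
    scenario = check_keys(scenario, c("n_records", "drift_param",
                                      "drift_rate", "noise_cv"), "scenario"),
    selection = check_keys(selection, c("target_size",
                                        "collinearity_threshold",
                                        "dominance_ratio"), "selection"),
    optimizer = check_keys(optimizer, c("sigma0", "popsize",
                                        "max_evaluations", "tol_cf"),
                           "optimizer"),
    trend = check_keys(trend, c("horizon", "min_fit_pct",
                                "modification_tol", "range_gate_factor",
                                "ts_grid", "max_order"), "trend"),
    validation = check_keys(validation, "at_grid", "validation"))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match the [run_config()]
#'   arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(cfg, stage, dir) {
  manifest <- list(stage = stage, seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, paste0("manifest_", stage,
                                                       ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing upstream artifact ", path,
         "; run the \"", produced_by, "\" command first")
  }
  path
}

#' Run the dynamic-fitting pipeline
#'
#' Orchestrates the full strategy with file-based handoff between stages,
#' so every intermediate is inspectable:
#' \describe{
#'   \item{synth}{generates the synthetic longitudinal study (records as
#'     CSV/JSON plus a ground-truth sidecar).}
#'   \item{fit}{standardizes and sequentially fits every record but the
#'     last (held out for validation), writing `fits.json`.}
#'   \item{trend}{identifies the ARX trend models and writes the
#'     per-parameter trend report.}
#'   \item{predict}{applies the justification gates and writes the
#'     predicted parameter values for the held-out record.}
#'   \item{validate}{compares time-specific, single-time and dynamic
#'     parameter sets on the held-out record and writes the validation
#'     report.}
#'   \item{all}{chains synth, fit, trend, predict, validate.}
#' }
#' Every stage writes a manifest with the configuration hash and seed;
#' reruns with identical configuration and seed reproduce the artifacts
#' byte for byte (timestamps aside).
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @param command one of `"synth"`, `"fit"`, `"trend"`, `"predict"`,
#'   `"validate"`, `"all"`.
#' @param model the physiological model; default [cr_surrogate()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list of artifact paths written by the command.
#' @export
run_pipeline <- function(config, command = c("all", "synth", "fit", "trend",
                                             "predict", "validate"),
                         model = cr_surrogate(), quiet = FALSE) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    records = config$records_dir,
    truth = file.path(config$out_dir, "truth.json"),
    fits = file.path(config$out_dir, "fits.json"),
    fits_rds = file.path(config$out_dir, "fit_state.rds"),
    trend_csv = file.path(config$out_dir, "trend_report.csv"),
    trend_json = file.path(config$out_dir, "trend_coefficients.json"),
    predictions = file.path(config$out_dir, "predicted_parameters.json"),
    validation = file.path(config$out_dir, "validation.json"),
    validation_csv = file.path(config$out_dir, "validation_per_variable.csv"))
  written <- list()

  if (command %in% c("synth", "all")) {
    say("synth: generating synthetic study")
    sc <- do.call(benchmark_scenario, c(list(seed = config$seed),
                                        config$scenario))
    for (rec in sc$records) write_record(rec, paths$records)
    write_truth_sidecar(sc$records, paths$truth)
    write_manifest(config, "synth", config$out_dir)
    written$records <- paths$records
    written$truth <- paths$truth
  }

  if (command %in% c("fit", "all")) {
    need_artifact(paths$records, "synth")
    records <- read_records(paths$records)
    say("fit: sequential time-specific fitting of ",
        length(records) - 1L, " records (last held out)")
    sel_args <- config$selection
    settings <- do.call(optimizer_settings,
                        c(list(seed = config$seed), config$optimizer))
    series <- do.call(fit_longitudinal,
                      c(list(model = model,
                             records = records[-length(records)],
                             settings = settings), sel_args))
    write_fit_series(series, paths$fits)
    saveRDS(series, paths$fits_rds)
    write_manifest(config, "fit", config$out_dir)
    written$fits <- paths$fits
  }

  if (command %in% c("trend", "predict", "all")) {
    need_artifact(paths$fits_rds, "fit")
    series <- readRDS(paths$fits_rds)
    records <- read_records(paths$records)
    horizon <- config$trend$horizon %||%
      (records[[length(records)]]$time_years -
         series$fits[[length(series$fits)]]$time_years)
    trend_cfg <- config$trend[setdiff(names(config$trend), "horizon")]
    say("trend/predict: ARX trend models, horizon ", horizon, " yr")
    outcomes <- do.call(predict_next_parameters,
                        c(list(series = series, horizon = horizon),
                          trend_cfg))
    export_trend_report(outcomes, paths$trend_csv, paths$trend_json)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = config_hash(config),
           time = attr(outcomes, "time"),
           values = lapply(outcomes, function(o) {
             list(status = o$status, value = o$value,
                  predicted = o$predicted_value)
           })),
      paths$predictions, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(config, "trend", config$out_dir)
    written$trend <- paths$trend_csv
    written$predictions <- paths$predictions
  }

  if (command %in% c("validate", "all")) {
    need_artifact(paths$fits_rds, "fit")
    need_artifact(paths$predictions, "trend")
    series <- readRDS(paths$fits_rds)
    records <- read_records(paths$records)
    held_out <- records[[length(records)]]
    say("validate: three-approach comparison on ", held_out$record_id)
    pred <- jsonlite::read_json(paths$predictions, simplifyVector = FALSE)
    last_fit <- series$fits[[length(series$fits)]]$params
    dynamic <- last_fit
    for (nm in names(pred$values)) {
      dynamic <- set_param_values(
        dynamic, pred$values[[nm]]$value, names = nm, clip = TRUE)
    }
    ## time-specific: fit the held-out record itself (upper benchmark)
    settings <- do.call(optimizer_settings,
                        c(list(seed = config$seed + 9999L),
                          config$optimizer))
    std <- standardize_record(held_out, last_fit)
    ts_fit <- fit_record(model, held_out, std, series$selection, settings)
    single_time <- series$fits[[1L]]$params
    at_grid <- config$validation$at_grid %||% "preceding"
    report <- compare_approaches(
      model, list(held_out),
      param_sets = list(time_specific = ts_fit$params,
                        single_time = single_time, dynamic = dynamic),
      at_grid = at_grid,
      preceding_at = records[[length(records) - 1L]]$at_vco2)
    export_validation_report(report, paths$validation,
                             paths$validation_csv)
    write_manifest(config, "validate", config$out_dir)
    written$validation <- paths$validation
  }
  invisible(written)
}
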