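## Simulates a candidate parameter set on a record's stimulus grid and
## scores it against the observations. Simulation failures (non-convergence
## or infeasible pattern) are penalized with a large finite cost instead of
## crashing the optimizer.
record_objective <- function(model, record, per_variable = NULL,
                             penalty = 1e6) {
  exp_data <- record$observations
  function(ps) {
    sim <- tryCatch(
      model$simulate(param_values(ps), record$stimulus$vo2,
                     record$stimulus$vco2),
      error = function(e) NULL)
    if (is.null(sim)) return(penalty)
    cb <- cost_function(exp_data, sim)
    if (is.null(per_variable)) cb$cf else cb$per_variable[[per_variable]]
  }
}

record_cost <- function(model, record, params) {
  sim <- model$simulate(param_values(params), record$stimulus$vo2,
                        record$stimulus$vco2)
  cost_function(record$observations, sim)
}

#' Fit the model to one longitudinal record
#'
#' Staged bounded optimization of the selected parameters against the
#' record's steady-state observations:
#' \describe{
#'   \item{Stage 1}{the base set is optimized jointly against the full
#'     relative-error cost with CMA-ES.}
#'   \item{Stage 2}{for each variable in the canonical order (`ve`, `vt`,
#'     `bf`, `ti`, `hr`, `ps`, `pm`, `pd`, `paco2`, `pao2`) with a nonempty
#'     specific set, that set is optimized against the variable's own mean
#'     squared relative error; the sub-result is accepted only if the
#'     overall cost does not worsen by more than `stage2_tol` relative and
#'     stays at or below the record's initial cost.}
#' }
#' A third, stimulus-related stage exists in the staging taxonomy but is
#' disabled: the stimulus-linked parameter group is not optimized.
#'
#' @param model a model object (see [cr_surrogate()]).
#' @param record a standardized [longitudinal_record()] with observations.
#' @param params_start a [parameter_set()]: the warm start (nominal values
#'   for the first record of a series, the previous optimum afterwards).
#' @param selection a [select_parameters()] result (or any list with
#'   `base_set` and `specific_sets`).
#' @param settings an [optimizer_settings()]; the evaluation budget default
#'   `500 * d` resolves per stage from the number of free parameters.
#' @param stage2_tol maximum tolerated relative degradation of the overall
#'   cost when accepting a variable-specific sub-result (default 0.01).
#' @return An object of class `fit_result`: list with `params`,
#'   `cf_initial`, `cf_final` (both [cost_function()] breakdowns),
#'   `stage_log` (data frame: stage, parameters touched, cf before/after,
#'   evaluations, seed, accepted) and `record_id`.
#' @export
fit_record <- function(model, record, params_start, selection,
                       settings = optimizer_settings(),
                       stage2_tol = 0.01) {
  stopifnot(inherits(record, "longitudinal_record"),
            !is.null(record$observations))
  cf_initial <- record_cost(model, record, params_start)
  log_rows <- list()
  push_log <- function(stage, touched, before, after, evals, seed, accepted) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, parameters = paste(touched, collapse = "+"),
      cf_before = before, cf_after = after, evaluations = evals,
      seed = seed, accepted = accepted)
  }

  ## Stage 1: base set against the full cost
  params <- params_start
  cf <- cf_initial$cf
  base <- selection$base_set
  if (length(base)) {
    s1 <- settings
    s1$seed <- settings$seed
    res <- cmaes_minimize(record_objective(model, record), params, base, s1)
    push_log("base", base, cf, res$cf, res$evaluations, s1$seed, TRUE)
    params <- res$params
    cf <- res$cf
  }

  ## Stage 2: per-variable specific sets, canonical order, guarded accept
  full_obj <- record_objective(model, record)
  for (vi in seq_along(model$variables)) {
    v <- model$variables[[vi]]
    free <- selection$specific_sets[[v]]
    if (!length(free)) next
    s2 <- settings
    s2$seed <- settings$seed + vi
    res <- cmaes_minimize(record_objective(model, record, per_variable = v),
                          params, free, s2)
    cf_cand <- full_obj(res$params)
    accept <- cf_cand <= cf * (1 + stage2_tol) && cf_cand <= cf_initial$cf
    push_log(paste0("specific:", v), free, cf, cf_cand, res$evaluations,
             s2$seed, accept)
    if (accept) {
      params <- res$params
      cf <- cf_cand
    }
  }

  cf_final <- record_cost(model, record, params)
  structure(list(params = params, cf_initial = cf_initial,
                 cf_final = cf_final,
                 stage_log = do.call(rbind, log_rows),
                 record_id = record$record_id,
                 time_years = record$time_years),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> record ", x$record_id, ": cf ",
      format(x$cf_initial$cf, digits = 4), " -> ",
      format(x$cf_final$cf, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Sequential time-specific fitting of a longitudinal series
#'
#' Chains [fit_record()] over a time-ordered series of records. The first
#' fit starts from the model's nominal parameter values; every subsequent
#' fit warm-starts from the immediately preceding optimization result.
#' Before each fit the parameter set is standardized to the record
#' ([standardize_record()]); optimization bounds stay anchored at the
#' nominal references throughout. The parameter selection is computed on
#' the first record and reused, so the tracked set is the same across the
#' series. Each iteration also registers the record's factor values for
#' later trend modeling.
#'
#' @inheritParams fit_record
#' @param records time-ordered list of standardizable records.
#' @param selection optional precomputed selection; by default
#'   [select_parameters()] is run on the first record.
#' @param ... passed on to [select_parameters()].
#' @return An object of class `fit_series`: list with `fits` (one
#'   [fit_record()] result per record), `selection`, and `factors` (data
#'   frame of time, activity, sleep and anaerobic threshold per record).
#' @export
fit_longitudinal <- function(model, records, settings = optimizer_settings(),
                             selection = NULL, ...) {
  times <- vapply(records, `[[`, 0, "time_years")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("records must be strictly ordered by time_years")
  }
  fits <- vector("list", length(records))
  params <- model$parameters          # nominal start for the first record
  factors <- data.frame()
  for (n in seq_along(records)) {
    rec <- records[[n]]
    params_n <- standardize_record(rec, params)
    if (is.null(selection)) {
      selection <- select_parameters(model, params_n, rec, ...)
    }
    s <- settings
    s$seed <- settings$seed + 101L * (n - 1L)
    fits[[n]] <- fit_record(model, rec, params_n, selection, settings = s)
    params <- fits[[n]]$params        # warm start for the next record
    factors <- rbind(factors, data.frame(
      record_id = rec$record_id, time = rec$time_years,
      activity = rec$factors$activity %||% NA_real_,
      sleep = rec$factors$sleep %||% NA_real_,
      at_vco2 = rec$at_vco2 %||% NA_real_))
  }
  structure(list(fits = fits, selection = selection, factors = factors),
            class = "fit_series")
}

#' @export
print.fit_series <- function(x, ...) {
  cat("<fit_series> ", length(x$fits), " records\n", sep = "")
  for (f in x$fits) print(f)
  invisible(x)
}

#' Serialize fit results to JSON
#'
#' @param series a [fit_longitudinal()] result.
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
write_fit_series <- function(series, path) {
  out <- list(
    selection = list(base_set = series$selection$base_set,
                     specific_sets = series$selection$specific_sets),
    factors = series$factors,
    fits = lapply(series$fits, function(f) {
      list(record_id = f$record_id, time_years = f$time_years,
           cf_initial = f$cf_initial$cf, cf_final = f$cf_final$cf,
           per_variable = as.list(f$cf_final$per_variable),
           params = as.list(param_values(f$params)),
           bounds = list(lower = stats::setNames(f$params$lower,
                                                 f$params$name),
                         upper = stats::setNames(f$params$upper,
                                                 f$params$name)),
           stage_log = f$stage_log)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
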