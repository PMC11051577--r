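#' Drift specification for synthetic true parameters
#'
#' Describes how each drifting parameter's true value evolves over a
#' subject's follow-up: a linear trend in time plus linear contributions of
#' the lifestyle factors and the anaerobic threshold, with optional AR(1)
#' innovations. Parameters not listed stay at their (standardized) nominal
#' values.
#'
#' @param names parameter names that drift.
#' @param slope per-year linear slopes (model units/year), recycled.
#' @param coef_activity,coef_sleep,coef_at linear factor coefficients
#'   (model units per h/week, per h/day, per L/min), recycled, default 0.
#' @param ar1_sd standard deviation of AR(1) innovations (model units),
#'   recycled, default 0.
#' @param ar1_phi AR(1) coefficient, default 0.7.
#' @return A data frame of class `drift_spec`.
#' @export
drift_spec <- function(names, slope = 0, coef_activity = 0, coef_sleep = 0,
                       coef_at = 0, ar1_sd = 0, ar1_phi = 0.7) {
  d <- data.frame(name = as.character(names),
                  slope = rep_len(slope, length(names)),
                  coef_activity = rep_len(coef_activity, length(names)),
                  coef_sleep = rep_len(coef_sleep, length(names)),
                  coef_at = rep_len(coef_at, length(names)),
                  ar1_sd = rep_len(ar1_sd, length(names)),
                  ar1_phi = rep_len(ar1_phi, length(names)))
  class(d) <- c("drift_spec", "data.frame")
  d
}

#' Synthetic longitudinal study design
#'
#' Shapes a synthetic study: how many subjects, when their records are
#' taken, their lifestyle-factor trajectories, anaerobic thresholds, the
#' stimulus grid resolution and the observation noise.
#'
#' @param n_subjects number of subjects.
#' @param times record times in years since each subject's first record
#'   (strictly increasing, first 0).
#' @param activity,sleep lifestyle factors: either vectors over records
#'   (recycled across subjects) or single values.
#' @param at_vco2 anaerobic threshold per record (L/min), recycled.
#' @param anthro list with `height` (cm), `weight` (kg), `age` (years) of
#'   the (first) subject.
#' @param vtn basal tidal volume measurement (L).
#' @param n_levels stimulus levels per record (default 8).
#' @param noise_cv coefficient of variation of the multiplicative
#'   observation noise (default 0.03).
#' @param rer respiratory exchange ratio mapping V̇CO2 to V̇O2.
#' @param seed integer seed for all generator randomness.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_subjects = 1L, times = c(0, 1, 2, 3),
                         activity = 5, sleep = 7, at_vco2 = 1.4,
                         anthro = list(height = 167.4, weight = 83.3,
                                       age = 30),
                         vtn = 0.6, n_levels = 8L, noise_cv = 0.03,
                         rer = 0.9, seed = 1L) {
  stopifnot(n_subjects >= 1L, n_levels >= 2L, noise_cv >= 0,
            !is.unsorted(times, strictly = TRUE), times[1L] == 0)
  structure(list(n_subjects = as.integer(n_subjects), times = times,
                 activity = rep_len(activity, length(times)),
                 sleep = rep_len(sleep, length(times)),
                 at_vco2 = rep_len(at_vco2, length(times)),
                 anthro = anthro, vtn = vtn,
                 n_levels = as.integer(n_levels), noise_cv = noise_cv,
                 rer = rer, seed = as.integer(seed)),
            class = "study_design")
}

#' Generate drifting true parameter trajectories
#'
#' Evaluates the drift law
#' `value(t) = intercept + slope*t + sum(coef * factor(t)) + AR(1) noise`
#' for every subject and record, where the intercept is the parameter's
#' nominal value and the factor contributions are measured as deviations
#' from the first record's factor values (so the first record of a constant
#' study sits exactly at nominal). Values are clipped into the parameter
#' bounds with a warning.
#'
#' @param spec a [drift_spec()].
#' @param design a [study_design()].
#' @param params the [parameter_set()] supplying nominals and bounds.
#' @return A list (one element per subject) of matrices
#'   `n_records x n_drifting` of true values, with parameter names as
#'   column names.
#' @export
generate_drift_trajectories <- function(spec, design, params) {
  i <- param_index(params, spec$name)
  n_rec <- length(design$times)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(design$seed)
  lapply(seq_len(design$n_subjects), function(s) {
    out <- matrix(0, n_rec, nrow(spec), dimnames = list(NULL, spec$name))
    for (j in seq_len(nrow(spec))) {
      base <- params$nominal[i[j]]
      det <- base + spec$slope[j] * design$times +
        spec$coef_activity[j] * (design$activity - design$activity[1L]) +
        spec$coef_sleep[j] * (design$sleep - design$sleep[1L]) +
        spec$coef_at[j] * (design$at_vco2 - design$at_vco2[1L])
      noise <- numeric(n_rec)
      if (spec$ar1_sd[j] > 0) {
        e <- stats::rnorm(n_rec, 0, spec$ar1_sd[j])
        for (n in seq_len(n_rec)) {
          noise[n] <- if (n == 1L) e[1L] else spec$ar1_phi[j] * noise[n - 1L] + e[n]
        }
      }
      v <- det + noise
      lo <- params$lower[i[j]]
      hi <- params$upper[i[j]]
      if (any(v < lo | v > hi)) {
        warning("drift trajectory for ", spec$name[j],
                " clipped into bounds")
        v <- pmin(pmax(v, lo), hi)
      }
      out[, j] <- v
    }
    out
  })
}

#' Generate a synthetic longitudinal study with known ground truth
#'
#' Builds the full synthetic fixture: for each subject and record, the true
#' parameter set is the standardized nominal set with the drifting
#' parameters replaced by their [generate_drift_trajectories()] values; the
#' model is simulated on the record's stimulus grid (equidistant V̇CO2 from
#' 0.3 L/min to the record's anaerobic threshold) and the observations are
#' the simulated outputs times multiplicative lognormal noise with
#' coefficient of variation `noise_cv` (mean-one noise). The hidden truth —
#' true parameter values per record — is attached as the `"truth"`
#' attribute and can be serialized to a sidecar file the fitting code never
#' reads.
#'
#' @param model a model object (see [cr_surrogate()]).
#' @param spec a [drift_spec()].
#' @param design a [study_design()].
#' @return A list of [longitudinal_record()] (subject-major, time-ordered
#'   within subject) with attribute `truth`: a list per subject of
#'   `n_records x n_params` matrices of true values for the drifting
#'   parameters, plus the standardized base set.
#' @export
generate_longitudinal_study <- function(model, spec, design) {
  truth_vals <- generate_drift_trajectories(spec, design, model$parameters)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(design$seed + 1L)
  records <- list()
  truth <- list()
  sdlog <- sqrt(log(1 + design$noise_cv^2))
  for (s in seq_len(design$n_subjects)) {
    subj_id <- sprintf("S%02d", s)
    subj_truth <- list()
    for (n in seq_along(design$times)) {
      rec_id <- sprintf("%s_r%d", subj_id, n)
      rec <- longitudinal_record(
        record_id = rec_id, subject_id = subj_id,
        time_years = design$times[n], anthro = design$anthro,
        env = list(fio2 = 21.0379, fico2 = 0.0421, patm = 640),
        factors = list(activity = design$activity[n],
                       sleep = design$sleep[n]),
        at_vco2 = design$at_vco2[n], vtn = design$vtn)
      true_params <- standardize_record(rec, model$parameters)
      true_params <- set_param_values(true_params, truth_vals[[s]][n, ],
                                      names = spec$name, clip = TRUE)
      grid <- stimulus_grid(design$at_vco2[n], design$n_levels,
                            rer = design$rer)
      clean <- tryCatch(
        model$simulate(param_values(true_params), grid$vo2, grid$vco2),
        error = function(e) {
          stop("synthetic generation failed for record ", rec_id, ": ",
               conditionMessage(e))
        })
      if (design$noise_cv > 0) {
        noise <- exp(stats::rnorm(length(clean), 0, sdlog) - sdlog^2 / 2)
        obs <- clean * noise
      } else {
        obs <- clean
      }
      rec$stimulus <- grid
      rec$observations <- obs
      records[[length(records) + 1L]] <- rec
      subj_truth[[rec_id]] <- param_values(true_params)
    }
    truth[[subj_id]] <- subj_truth
  }
  attr(records, "truth") <- truth
  records
}

#' The benchmark drifting-gain scenario
#'
#' Canonical synthetic scenario used by the package's end-to-end checks:
#' one subject followed over four annual records, the metabolic ventilatory
#' gain `Gm` drifting linearly at 5% of nominal per year, all other
#' parameters constant, 3% multiplicative observation noise, and the
#' standard 8-level stimulus grid up to an anaerobic threshold of
#' 1.4 L/min.
#'
#' @param seed integer seed.
#' @param n_records number of annual records (default 4).
#' @param drift_param which gain drifts (default `"Gm"`).
#' @param drift_rate drift per year as a fraction of nominal (default 0.05).
#' @param noise_cv observation noise CV (default 0.03).
#' @return List with `spec`, `design`, and the generated `records` (with
#'   `truth` attribute) for the surrogate model.
#' @export
benchmark_scenario <- function(seed = 1L, n_records = 4L,
                               drift_param = "Gm", drift_rate = 0.05,
                               noise_cv = 0.03) {
  model <- cr_surrogate()
  nom <- model$parameters$nominal[param_index(model$parameters, drift_param)]
  spec <- drift_spec(drift_param, slope = drift_rate * nom)
  design <- study_design(n_subjects = 1L, times = seq(0, n_records - 1L),
                         noise_cv = noise_cv, seed = seed)
  records <- generate_longitudinal_study(model, spec, design)
  list(model = model, spec = spec, design = design, records = records)
}

#' Parameter recovery report
#'
#' Scores fitted parameter values against the hidden truth of a synthetic
#' study: per parameter and record, the relative error
#' `|fitted - true| / |true|`, with mean and max summaries per parameter.
#'
#' @param truth named list per record of named true value vectors (one
#'   subject's entry of the `truth` attribute of
#'   [generate_longitudinal_study()]).
#' @param fits list of [fit_record()] results aligned with `truth`.
#' @param names parameter names to score; default the intersection of
#'   fitted and true names.
#' @return Data frame with columns `name`, `record`, `true`, `fitted`,
#'   `rel_error`, plus attribute `summary` (per-parameter mean/max).
#' @export
parameter_recovery_report <- function(truth, fits, names = NULL) {
  stopifnot(length(truth) == length(fits))
  rows <- list()
  for (n in seq_along(fits)) {
    tv <- truth[[n]]
    fv <- param_values(fits[[n]]$params)
    nm <- names %||% intersect(base::names(fv), base::names(tv))
    if (!length(nm)) next
    rows[[n]] <- data.frame(name = nm, record = n, true = unname(tv[nm]),
                            fitted = unname(fv[nm]),
                            rel_error = abs(fv[nm] - tv[nm]) / abs(tv[nm]),
                            row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(name = character(), record = integer(),
                                      true = numeric(), fitted = numeric(),
                                      rel_error = numeric())
  summary <- if (nrow(out)) {
    agg <- stats::aggregate(rel_error ~ name, out,
                            function(x) c(mean = mean(x), max = max(x)))
    data.frame(name = agg$name, mean = agg$rel_error[, "mean"],
               max = agg$rel_error[, "max"])
  } else {
    data.frame(name = character(), mean = numeric(), max = numeric())
  }
  attr(out, "summary") <- summary
  out
}

#' Serialize the hidden truth of a synthetic study
#'
#' Writes the ground-truth parameter values of a synthetic study to a
#' sidecar JSON file, kept apart from the record files so that fitting code
#' paths never see it.
#'
#' @param records a [generate_longitudinal_study()] result.
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
write_truth_sidecar <- function(records, path) {
  truth <- attr(records, "truth")
  if (is.null(truth)) stop("records carry no truth attribute")
  jsonlite::write_json(lapply(truth, function(s) lapply(s, as.list)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
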