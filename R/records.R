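#' Longitudinal study records
#'
#' One longitudinal record holds everything measured at one time point of a
#' subject's follow-up: anthropometrics, environment, lifestyle factors,
#' anaerobic threshold, the exercise stimulus grid, and the steady-state
#' observations of the ten cardiorespiratory variables on that grid.
#'
#' @param record_id unique record identifier.
#' @param subject_id subject identifier.
#' @param time_years time of the record in years since the subject's first
#'   record (first record = 0).
#' @param anthro list with `height` (cm), `weight` (kg), `age` (years).
#' @param env list with `fio2` (%), `fico2` (%), `patm` (mmHg).
#' @param factors list with `activity` (h/week) and `sleep` (h/day).
#' @param at_vco2 anaerobic threshold expressed as V̇CO2 (L/min), or `NULL`
#'   when a `breath_series` is supplied instead.
#' @param vtn basal tidal volume measurement (L).
#' @param stimulus data frame with columns `vo2`, `vco2` (L/min): the
#'   exercise stimulus grid, ordered by increasing intensity.
#' @param observations numeric matrix `K x 10` (stimulus levels by
#'   variables, columns named as [cr_variables()]), or `NULL` for a record
#'   awaiting simulation.
#' @param breath_series optional list with `vo2`, `vco2` sample vectors for
#'   v-slope estimation of the anaerobic threshold.
#' @return An object of class `longitudinal_record`.
#' @export
longitudinal_record <- function(record_id, subject_id, time_years, anthro,
                                env, factors, at_vco2 = NULL, vtn = NULL,
                                stimulus = NULL, observations = NULL,
                                breath_series = NULL) {
  if (!is.null(observations)) {
    observations <- as.matrix(observations)
    if (is.null(colnames(observations)) ||
        !all(CR_VARIABLES %in% colnames(observations))) {
      stop("observations must have the ten variable columns: ",
           paste(CR_VARIABLES, collapse = ", "))
    }
    observations <- observations[, CR_VARIABLES, drop = FALSE]
    if (!is.null(stimulus) && nrow(observations) != nrow(stimulus)) {
      stop("observations and stimulus grid disagree in length")
    }
  }
  rec <- list(record_id = record_id, subject_id = subject_id,
              time_years = as.numeric(time_years), anthro = anthro,
              env = env, factors = factors, at_vco2 = at_vco2, vtn = vtn,
              stimulus = stimulus, observations = observations,
              breath_series = breath_series)
  class(rec) <- "longitudinal_record"
  rec
}

#' @export
print.longitudinal_record <- function(x, ...) {
  cat("<longitudinal_record> ", x$record_id, " (subject ", x$subject_id,
      ", t = ", x$time_years, " yr)\n", sep = "")
  if (!is.null(x$stimulus)) {
    cat("  stimulus grid: ", nrow(x$stimulus), " levels, vco2 ",
        min(x$stimulus$vco2), "-", max(x$stimulus$vco2), " L/min\n", sep = "")
  }
  invisible(x)
}

#' Exercise stimulus grid from rest to the anaerobic threshold
#'
#' Builds the grid of incremental exercise stimulus levels used for fitting
#' and validation: `n_levels` consecutive, equidistant V̇CO2 values starting
#' at 0.3 L/min (the resting reference) and ending at the anaerobic
#' threshold, with V̇O2 derived through a fixed respiratory exchange ratio.
#'
#' @param at_vco2 anaerobic threshold as V̇CO2 (L/min), > 0.3.
#' @param n_levels number of levels (default 8).
#' @param rer respiratory exchange ratio V̇CO2/V̇O2 used to map V̇CO2 to
#'   V̇O2 (default 0.9, typical of moderate aerobic exercise).
#' @return Data frame with columns `vo2`, `vco2`.
#' @export
stimulus_grid <- function(at_vco2, n_levels = 8L, rer = 0.9) {
  stopifnot(at_vco2 > 0.3, n_levels >= 2L, rer > 0)
  vco2 <- seq(0.3, at_vco2, length.out = n_levels)
  data.frame(vo2 = vco2 / rer, vco2 = vco2)
}

record_csv_path <- function(dir, record_id) {
  file.path(dir, paste0(record_id, ".csv"))
}
record_json_path <- function(dir, record_id) {
  file.path(dir, paste0(record_id, ".json"))
}

#' Read and write longitudinal records
#'
#' Records are exchanged as one CSV per record (long format, one row per
#' variable and stimulus level, columns `record_id`, `subject_id`,
#' `time_years`, `variable`, `stimulus_vo2`, `stimulus_vco2`, `value`;
#' UTF-8, comma separator, "." decimal) plus a companion JSON file with the
#' anthropometrics, environment, factors, anaerobic threshold and basal
#' tidal volume.
#'
#' @param record a [longitudinal_record()].
#' @param dir directory holding the record files.
#' @return `write_record()` invisibly returns the two file paths;
#'   `read_record()` returns a `longitudinal_record`; `read_records()`
#'   returns a time-ordered list of them.
#' @export
write_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(!is.null(record$stimulus), !is.null(record$observations))
  k <- nrow(record$stimulus)
  long <- data.frame(
    record_id = record$record_id, subject_id = record$subject_id,
    time_years = record$time_years,
    variable = rep(colnames(record$observations), each = k),
    stimulus_vo2 = rep(record$stimulus$vo2, ncol(record$observations)),
    stimulus_vco2 = rep(record$stimulus$vco2, ncol(record$observations)),
    value = as.vector(record$observations))
  csv <- record_csv_path(dir, record$record_id)
  utils::write.csv(long, csv, row.names = FALSE, fileEncoding = "UTF-8")
  meta <- list(record_id = record$record_id, subject_id = record$subject_id,
               time_years = record$time_years, anthro = record$anthro,
               env = record$env, factors = record$factors,
               at_vco2 = record$at_vco2, vtn = record$vtn)
  json <- record_json_path(dir, record$record_id)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(csv = csv, json = json))
}

#' @rdname write_record
#' @param record_id identifier of the record to read.
#' @export
read_record <- function(dir, record_id) {
  csv <- record_csv_path(dir, record_id)
  json <- record_json_path(dir, record_id)
  if (!file.exists(csv) || !file.exists(json)) {
    stop("record files not found for \"", record_id, "\" under ", dir)
  }
  long <- utils::read.csv(csv, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  vars <- unique(long$variable)
  k <- sum(long$variable == vars[1L])
  obs <- matrix(long$value, nrow = k, ncol = length(vars),
                dimnames = list(NULL, vars))
  stim <- data.frame(vo2 = long$stimulus_vo2[seq_len(k)],
                     vco2 = long$stimulus_vco2[seq_len(k)])
  longitudinal_record(record_id = meta$record_id,
                      subject_id = meta$subject_id,
                      time_years = meta$time_years,
                      anthro = as.list(meta$anthro), env = as.list(meta$env),
                      factors = as.list(meta$factors),
                      at_vco2 = meta$at_vco2, vtn = meta$vtn,
                      stimulus = stim, observations = obs)
}

#' @rdname write_record
#' @export
read_records <- function(dir) {
  csvs <- list.files(dir, pattern = "\\.csv$", full.names = FALSE)
  ids <- sub("\\.csv$", "", csvs)
  ids <- ids[file.exists(record_json_path(dir, ids))]
  if (!length(ids)) stop("no records found under ", dir)
  recs <- lapply(ids, function(id) read_record(dir, id))
  recs[order(vapply(recs, `[[`, 0, "time_years"))]
}
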