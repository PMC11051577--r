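#' Body surface area and total blood volume from anthropometrics
#'
#' Computes body surface area by the square-root height-weight rule
#' `BSA = sqrt(weight * height / 3600)` (weight in kg, height in cm, BSA in
#' m^2) and total blood volume by the linear BSA rule
#' `Vtot = 1000 * (3.29 * BSA - 1.29)` (mL). These are the two equations used
#' to standardize the simulation conditions of each longitudinal record.
#'
#' @param height height in cm.
#' @param weight weight in kg.
#' @return A list with elements `bsa` (m^2) and `vtot` (mL).
#' @examples
#' compute_bsa_vtot(height = 163.0, weight = 71.8)$vtot # 4642.0 mL
#' @export
compute_bsa_vtot <- function(height, weight) {
  stopifnot(is.numeric(height), is.numeric(weight))
  if (any(height <= 0) || any(weight <= 0)) {
    stop("height and weight must be positive")
  }
  bsa <- sqrt(weight * height / 3600)
  vtot <- 1000 * (3.29 * bsa - 1.29)
  if (any(vtot <= 0)) {
    stop("nonphysical anthropometrics: 3.29*BSA <= 1.29 gives Vtot <= 0")
  }
  list(bsa = bsa, vtot = vtot)
}

#' Scale a group of volume parameters in proportion to total blood volume
#'
#' The unstressed blood-volume parameters are assigned per record using the
#' proportion of their nominal values with respect to the nominal total blood
#' volume: each grouped parameter's value becomes
#' `nominal * vtot_subject / vtot_nominal`. Parameters outside the group are
#' untouched.
#'
#' @param params a [parameter_set()].
#' @param group character vector of parameter names to scale (may be empty).
#' @param vtot_subject the record's total blood volume (mL).
#' @param vtot_nominal the model's nominal total blood volume (mL).
#' @return The updated `parameter_set`.
#' @export
scale_volume_group <- function(params, group, vtot_subject, vtot_nominal) {
  stopifnot(vtot_nominal > 0, vtot_subject > 0)
  if (length(group) == 0L) return(params)
  i <- param_index(params, group)
  ratio <- vtot_subject / vtot_nominal
  params$value[i] <- params$nominal[i] * ratio
  ## keep the bound invariant: rescale the group's reference alongside
  params$nominal[i] <- params$nominal[i] * ratio
  params$lower[i] <- params$lower[i] * ratio
  params$upper[i] <- params$upper[i] * ratio
  validate_parameter_set(params)
  params
}

#' Anaerobic threshold by the v-slope method
#'
#' Estimates the anaerobic threshold from paired steady O2-uptake /
#' CO2-output samples ordered by increasing work, as the breakpoint of a
#' two-segment piecewise-linear least-squares fit of CO2 output against O2
#' uptake (the v-slope construction). Every interior sample with at least
#' `min_points` samples on each side is tried as the shared breakpoint; the
#' breakpoint minimizing the total sum of squared errors, among those where
#' the upper segment is strictly steeper than the lower one, is returned as
#' its CO2-output value.
#'
#' @param vo2,vco2 numeric vectors of equal length (>= 6), positive,
#'   ordered by increasing work (L/min).
#' @param min_points minimum samples per segment (default 3).
#' @return The anaerobic threshold expressed as V̇CO2 (L/min).
#' @examples
#' vo2 <- seq(0.4, 2, length.out = 20)
#' vco2 <- ifelse(vo2 <= 1.2, 0.9 * vo2, 0.9 * 1.2 + 1.3 * (vo2 - 1.2))
#' estimate_at_vslope(vo2, vco2)
#' @export
estimate_at_vslope <- function(vo2, vco2, min_points = 3L) {
  n <- length(vo2)
  if (length(vco2) != n) stop("vo2 and vco2 must have equal length")
  if (n < 2L * min_points) {
    stop("breath series too short: need at least ", 2L * min_points,
         " samples")
  }
  if (any(vo2 <= 0) || any(vco2 <= 0)) stop("breath samples must be positive")
  seg_fit <- function(idx) {
    f <- stats::lm.fit(cbind(1, vo2[idx]), vco2[idx])
    list(slope = f$coefficients[2L], sse = sum(f$residuals^2))
  }
  best <- NULL
  for (b in seq.int(min_points, n - min_points + 1L)) {
    lo <- seg_fit(seq_len(b))
    hi <- seg_fit(seq.int(b, n))
    if (!(hi$slope > lo$slope + 1e-9 * (1 + abs(lo$slope)))) next
    sse <- lo$sse + hi$sse
    if (is.null(best) || sse < best$sse - 1e-15) best <- list(sse = sse, b = b)
  }
  if (is.null(best)) {
    stop("degenerate breath series: no breakpoint with a slope increase ",
         "(v-slope undefined)")
  }
  vco2[best$b]
}

req_field <- function(record, field, where = field) {
  v <- record[[field]]
  if (is.null(v) || (is.atomic(v) && all(is.na(v)))) {
    stop("record ", record$record_id %||% "?",
         ": missing required field \"", where, "\"")
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize a parameter set to one longitudinal record
#'
#' Assigns the measurement-derived parameters of a record before fitting:
#' the environmental conditions (`fio2`, `fico2`, `patm`), the basal tidal
#' volume `VTn`, the anaerobic threshold `AT` (taken directly from the record
#' when present, otherwise estimated from its breath series by
#' [estimate_at_vslope()]), the total blood volume `Vtot` from the record's
#' anthropometrics via [compute_bsa_vtot()], and the unstressed blood-volume
#' group scaled in proportion to `Vtot`. All other parameters are left
#' unchanged, so the operation is idempotent.
#'
#' @param record a [longitudinal_record()].
#' @param params a [parameter_set()] containing the standardization targets.
#' @param volume_group names of the blood-volume parameters scaled with
#'   `Vtot`.
#' @return The standardized `parameter_set`.
#' @export
standardize_record <- function(record, params,
                               volume_group = c("Vu_ven", "Vu_art")) {
  stopifnot(inherits(record, "longitudinal_record"))
  env <- req_field(record, "env")
  for (f in c("fio2", "fico2", "patm")) {
    if (is.null(env[[f]])) {
      stop("record ", record$record_id, ": missing required field \"", f, "\"")
    }
  }
  anthro <- req_field(record, "anthro")
  height <- anthro$height
  weight <- anthro$weight
  if (is.null(height)) stop("record ", record$record_id,
                            ": missing required field \"height\"")
  if (is.null(weight)) stop("record ", record$record_id,
                            ": missing required field \"weight\"")
  vtn <- req_field(record, "vtn")
  at <- record$at_vco2
  if (is.null(at)) {
    bs <- record$breath_series
    if (is.null(bs)) {
      stop("record ", record$record_id,
           ": missing required field \"at_vco2\" (no breath series either)")
    }
    at <- estimate_at_vslope(bs$vo2, bs$vco2)
  }
  bv <- compute_bsa_vtot(height, weight)
  vtot_nominal <- params$nominal[param_index(params, "Vtot")]
  assign_std <- function(ps, name, value) {
    i <- param_index(ps, name)
    ps$value[i] <- value
    ## assigned parameters take the measurement as their new reference
    ps$nominal[i] <- value
    w <- ifelse(ps$measure_linked[i], 0.30, 0.50)
    ps$lower[i] <- value - abs(value) * w
    ps$upper[i] <- value + abs(value) * w
    ps
  }
  params <- assign_std(params, "fio2", env$fio2)
  params <- assign_std(params, "fico2", env$fico2)
  params <- assign_std(params, "patm", env$patm)
  params <- assign_std(params, "VTn", vtn)
  params <- assign_std(params, "AT", at)
  params <- assign_std(params, "Vtot", bv$vtot)
  params <- scale_volume_group(params, volume_group, bv$vtot, vtot_nominal)
  validate_parameter_set(params)
  params
}
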