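#' @keywords internal
"_PACKAGE"

## Canonical order of the ten steady-state cardiorespiratory variables.
## This order is used everywhere: simulation outputs, cost breakdowns,
## sensitivity rows, stage-2 refinement and validation reports.
CR_VARIABLES <- c("ve", "vt", "bf", "ti", "hr", "ps", "pm", "pd",
                  "paco2", "pao2")

#' Steady-state variable names
#'
#' The ten cardiorespiratory variables predicted at steady state, in the
#' canonical order used throughout the package: minute ventilation `ve`
#' (L/min), tidal volume `vt` (L), breathing frequency `bf` (1/min),
#' inspiratory time `ti` (s), heart rate `hr` (bpm), systolic/mean/diastolic
#' arterial pressures `ps`, `pm`, `pd` (mmHg), and alveolar CO2/O2 partial
#' pressures `paco2`, `pao2` (mmHg).
#'
#' @return Character vector of length 10.
#' @export
cr_variables <- function() CR_VARIABLES

#' Default parameter table of the demonstration model
#'
#' Builds the [parameter_set()] of the compact self-regulated steady-state
#' cardiorespiratory demonstration model. The nominal values are
#' artifact-chosen plausible resting/exercise physiology for a healthy adult
#' at moderate altitude; they are not the values of any published
#' multi-compartment cardiorespiratory model.
#'
#' Parameter roles:
#' \describe{
#'   \item{gain_threshold}{controller gains and thresholds
#'     (`Gc`, `Gp`, `Gm`, `kVT`, `GHR`, `GPM`, `GPP`, `Bc`, `KpO2`, `rI`,
#'     `VTmax`) — the only parameters eligible for optimization.}
#'   \item{covariate}{measurement-assigned quantities (`VTn`, `VEn`, `HR0`,
#'     `PM0`, `PP0`, `V0dead`, `fio2`, `fico2`, `patm`, `AT`, `Vtot`).}
#'   \item{initial_value}{unstressed blood volumes (`Vu_ven`, `Vu_art`),
#'     scaled in proportion to total blood volume during standardization.}
#'   \item{time_constant}{`tau_hr` (heart-rate response time constant; inert
#'     at steady state, kept to exercise the role taxonomy).}
#'   \item{conversion}{`c_gas`, the STPD-to-BTPS alveolar gas conversion
#'     factor (mmHg per L/min per L/min of alveolar ventilation).}
#' }
#'
#' @return A [parameter_set()] with 25 parameters.
#' @export
cr_surrogate_parameters <- function() {
  p <- list(
    ## name,    nominal,  role,            measure_linked
    list("Gc",     0.5,   "gain_threshold", FALSE), # central CO2 gain (L/min/mmHg)
    list("Bc",    36.0,   "gain_threshold", TRUE),  # central CO2 threshold (mmHg)
    list("Gp",    30.0,   "gain_threshold", FALSE), # peripheral hypoxic gain (L/min)
    list("KpO2",  30.0,   "gain_threshold", FALSE), # hypoxic response shape (mmHg)
    list("Gm",    20.0,   "gain_threshold", FALSE), # metabolic ventilatory gain
    list("kVT",    0.03,  "gain_threshold", FALSE), # tidal volume recruitment (L per L/min)
    list("VTmax",  2.5,   "gain_threshold", TRUE),  # tidal volume ceiling (L)
    list("rI",     0.4,   "gain_threshold", TRUE),  # inspiratory duty fraction
    list("GHR",   40.0,   "gain_threshold", FALSE), # heart-rate gain (bpm per L/min O2)
    list("GPM",   20.0,   "gain_threshold", FALSE), # mean pressure gain (mmHg per L/min)
    list("GPP",   45.0,   "gain_threshold", FALSE), # pulse pressure gain (mmHg per L/min)
    list("VTn",    0.6,   "covariate",      TRUE),  # basal tidal volume (L)
    list("VEn",    8.0,   "covariate",      TRUE),  # basal minute ventilation (L/min)
    list("HR0",   60.0,   "covariate",      TRUE),  # resting heart rate (bpm)
    list("PM0",   85.0,   "covariate",      TRUE),  # resting mean pressure (mmHg)
    list("PP0",   28.0,   "covariate",      TRUE),  # resting pulse pressure (mmHg)
    list("V0dead", 0.15,  "covariate",      TRUE),  # series dead space (L)
    list("fio2",  21.0379,"covariate",      TRUE),  # inspired O2 fraction (%)
    list("fico2",  0.0421,"covariate",      TRUE),  # inspired CO2 fraction (%)
    list("patm", 640.0,   "covariate",      TRUE),  # atmospheric pressure (mmHg)
    list("AT",     1.4,   "covariate",      TRUE),  # anaerobic threshold (L/min CO2)
    list("Vtot", 5000.0,  "covariate",      TRUE),  # total blood volume (mL)
    list("Vu_ven", 3200.0,"initial_value",  FALSE), # unstressed venous volume (mL)
    list("Vu_art",  700.0,"initial_value",  FALSE), # unstressed arterial volume (mL)
    list("tau_hr", 30.0,  "time_constant",  FALSE), # HR time constant (s)
    list("c_gas", 863.0,  "conversion",     TRUE)   # gas conversion factor
  )
  parameter_set(name = vapply(p, `[[`, "", 1L),
                nominal = vapply(p, `[[`, 0, 2L),
                role = vapply(p, `[[`, "", 3L),
                measure_linked = vapply(p, function(x) x[[4L]], NA))
}

#' The demonstration cardiorespiratory model
#'
#' Constructs the compact self-regulated steady-state model used as the
#' test-bed "physiological model" throughout the package. Exercise stimulus
#' (O2 uptake and CO2 output) drives a ventilatory chemoreflex-plus-metabolic
#' controller closed through the alveolar gas-balance equations; the
#' resulting ventilation sets the breathing pattern, and linear
#' cardiovascular responses set heart rate and arterial pressures.
#'
#' Any model exposing the same contract can replace it in every downstream
#' function: a list with elements `name`, `parameters` (a [parameter_set()]),
#' `variables` (output names) and `simulate(values, vo2, vco2)` returning a
#' `length(vo2) x length(variables)` matrix, where `values` is the named
#' vector of all current parameter values. A full multi-compartment
#' cardiorespiratory model can be plugged in this way.
#'
#' @param parameters optional [parameter_set()] overriding
#'   [cr_surrogate_parameters()].
#' @return An object of class `cr_model`.
#' @export
cr_surrogate <- function(parameters = cr_surrogate_parameters()) {
  model <- list(name = "cr_surrogate",
                parameters = parameters,
                variables = CR_VARIABLES,
                simulate = function(values, vo2, vco2) {
                  surrogate_simulate(values, vo2, vco2)
                })
  class(model) <- "cr_model"
  model
}

#' @export
print.cr_model <- function(x, ...) {
  cat("<cr_model> ", x$name, ": ", nrow(x$parameters), " parameters, ",
      length(x$variables), " steady-state variables\n", sep = "")
  invisible(x)
}

## Ventilatory controller output for candidate ventilation ve (vectorized
## over stimulus levels). Returns the controller ventilation demand given the
## alveolar gases implied by ve, plus the implied pattern variables.
surrogate_controller <- function(v, ve, vo2, vco2) {
  pb <- v[["patm"]] - 47                       # water-vapor corrected
  pio2 <- v[["fio2"]] / 100 * pb
  pico2 <- v[["fico2"]] / 100 * pb
  vt <- pmin(pmax(v[["VTn"]] + v[["kVT"]] * (ve - v[["VEn"]]), v[["VTn"]]),
             v[["VTmax"]])
  if (any(vt <= v[["V0dead"]])) {
    stop("infeasible breathing pattern: tidal volume at or below dead space")
  }
  va <- ve * (1 - v[["V0dead"]] / vt)          # alveolar ventilation
  paco2 <- pico2 + v[["c_gas"]] * vco2 / va
  pao2 <- pio2 - v[["c_gas"]] * vo2 / va
  demand <- pmax(0.5, v[["Gc"]] * (paco2 - v[["Bc"]]) +
                   v[["Gp"]] * exp(-pao2 / v[["KpO2"]]) +
                   v[["Gm"]] * vco2)
  list(demand = demand, vt = vt, va = va, paco2 = paco2, pao2 = pao2)
}

## Solves the scalar ventilation fixed point ve = controller(ve) for every
## stimulus level at once. The controller demand is monotone nonincreasing
## in ve and floored at 0.5 L/min, so the residual r(ve) = ve - demand(ve)
## is monotone increasing with r(0.5) <= 0: the root is unique and
## bracketable. It is found per level by a bracketed secant (Illinois)
## update, all levels iterated together, which needs an order of magnitude
## fewer controller evaluations than a damped fixed-point sweep.
surrogate_solve_ve <- function(v, vo2, vco2, tol = 1e-6, max_iter = 500L) {
  k <- length(vo2)
  residual <- function(ve) ve - surrogate_controller(v, ve, vo2, vco2)$demand
  guess <- pmax(10, v[["Gm"]] * vco2)  # demand-scale initial guess
  a <- b <- guess
  fa <- fb <- residual(guess)
  it <- 0L
  ## geometric expansion to a sign-changing bracket [a, b] around the guess
  while ((any(fa > 0) || any(fb < 0)) && it < 60L) {
    down <- fa > 0
    a[down] <- pmax(a[down] / 2, 0.5)  # r(0.5) <= 0: the demand floor
    up <- fb < 0
    b[up] <- b[up] * 2
    f_new <- residual(ifelse(down, a, b))
    fa[down] <- f_new[down]
    fb[up] <- f_new[up]
    it <- it + 1L
  }
  if (any(fa > 0) || any(fb < 0)) {
    j <- which(fa > 0 | fb < 0)[1L]
    stop(sprintf("ventilation demand unbracketable at stimulus vo2=%.3f, vco2=%.3f",
                 vo2[j], vco2[j]))
  }
  side <- integer(k)                   # Illinois: track retained side
  x <- b
  fx <- fb
  for (it in seq_len(max_iter)) {
    x <- b - fb * (b - a) / (fb - fa)
    bad <- !is.finite(x) | x <= a | x >= b
    x[bad] <- (a[bad] + b[bad]) / 2
    fx <- residual(x)
    if (all(abs(fx) < tol)) {
      ctrl <- surrogate_controller(v, x, vo2, vco2)
      return(list(ve = x, ctrl = ctrl, iterations = it))
    }
    neg <- fx < 0
    ## root above x: move lower bracket; Illinois-halve fb if b retained twice
    a[neg] <- x[neg]
    fa[neg] <- fx[neg]
    fb[neg & side == 1L] <- fb[neg & side == 1L] / 2
    b[!neg] <- x[!neg]
    fb[!neg] <- fx[!neg]
    fa[!neg & side == -1L] <- fa[!neg & side == -1L] / 2
    side[neg] <- 1L
    side[!neg] <- -1L
  }
  stop(sprintf(paste0("ventilation fixed point did not converge within %d ",
                      "iterations at stimulus vo2=%.3f, vco2=%.3f ",
                      "(residual %.3g L/min)"),
               max_iter, vo2[which.max(abs(fx))], vco2[which.max(abs(fx))],
               max(abs(fx))))
}

## Full steady-state response of the surrogate for vectors of stimulus
## levels. Returns a K x 10 matrix in canonical variable order.
surrogate_simulate <- function(values, vo2, vco2, tol = 1e-6,
                               max_iter = 500L) {
  stopifnot(length(vo2) == length(vco2))
  if (any(vo2 <= 0) || any(vco2 <= 0)) stop("stimulus levels must be positive")
  sol <- surrogate_solve_ve(values, vo2, vco2, tol = tol, max_iter = max_iter)
  ve <- sol$ve
  ctrl <- sol$ctrl
  bf <- ve / ctrl$vt
  ti <- 60 * values[["rI"]] / bf
  hr <- values[["HR0"]] + values[["GHR"]] * vo2
  pm <- values[["PM0"]] + values[["GPM"]] * vo2
  pp <- values[["PP0"]] + values[["GPP"]] * vo2
  pd <- pm - pp / 3
  ps <- pd + pp
  out <- cbind(ve = ve, vt = ctrl$vt, bf = bf, ti = ti, hr = hr, ps = ps,
               pm = pm, pd = pd, paco2 = ctrl$paco2, pao2 = ctrl$pao2)
  rownames(out) <- NULL
  out
}

## Merges an explicit environment specification into the value vector.
apply_env <- function(values, env) {
  if (is.null(env)) return(values)
  stopifnot(is.list(env))
  for (f in intersect(c("fio2", "fico2", "patm"), names(env))) {
    values[[f]] <- env[[f]]
  }
  values
}

#' Simulate the steady-state response at one stimulus level
#'
#' Solves the model's ventilation fixed point and returns the ten
#' steady-state variables. The environment (inspired gas fractions and
#' barometric pressure) lives in the parameter set; an explicit `env`
#' argument overrides it for the call.
#'
#' @param model a model object such as [cr_surrogate()].
#' @param params a [parameter_set()]; defaults to the model's own.
#' @param vo2,vco2 stimulus level: O2 uptake and CO2 output (L/min). May be
#'   vectors of equal length (a stimulus grid).
#' @param env optional list with elements `fio2` (%), `fico2` (%), `patm`
#'   (mmHg).
#' @return A named numeric vector (single level) or a `K x 10` matrix (grid)
#'   of the variables in [cr_variables()] order.
#' @examples
#' m <- cr_surrogate()
#' simulate_steady_state(m, vo2 = 0.3, vco2 = 0.3)
#' @export
simulate_steady_state <- function(model, params = model$parameters,
                                  vo2, vco2, env = NULL) {
  v <- apply_env(param_values(params), env)
  out <- model$simulate(v, vo2, vco2)
  if (length(vo2) == 1L) out[1L, ] else out
}

#' Ventilation fixed-point residual
#'
#' Exposes the scalar equation solved by [simulate_steady_state()]:
#' the difference between a candidate minute ventilation and the controller
#' demand implied by the alveolar gases that candidate produces. The steady
#' state is the root of this function; it is monotone increasing in
#' `ve_candidate`, which makes it bracketable and usable as an independent
#' check on the solver.
#'
#' @param ve_candidate candidate minute ventilation (L/min), positive.
#' @inheritParams simulate_steady_state
#' @return `ve_candidate - demand(ve_candidate)` in L/min.
#' @export
ventilation_residual <- function(ve_candidate, model, params = model$parameters,
                                 vo2, vco2, env = NULL) {
  stopifnot(length(vo2) == 1L, length(vco2) == 1L)
  if (any(ve_candidate <= 0)) stop("ve_candidate must be positive")
  v <- apply_env(param_values(params), env)
  ctrl <- surrogate_controller(v, ve_candidate, rep(vo2, length(ve_candidate)),
                               rep(vco2, length(ve_candidate)))
  ve_candidate - ctrl$demand
}
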