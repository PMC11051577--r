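#' Relative-error cost of a simulated record
#'
#' The fitting cost is the mean over variables of the mean over stimulus
#' levels of the squared relative error:
#' `CF = (1/I) * sum_i (1/K) * sum_k ((yexp - ysim)/yexp)^2`,
#' with `I` variables and `K` stimulus levels. The cost is dimensionless,
#' zero exactly when simulation equals experiment, and invariant to
#' rescaling any variable's experimental and simulated series by a common
#' positive factor. A square-root variant (root mean of the same squared
#' relative errors) is available through `sqrt_metric`.
#'
#' @param exp_data,sim_data numeric matrices `K x I` (stimulus levels by
#'   variables) with matching dimensions and column names.
#' @param sqrt_metric if `TRUE`, report `sqrt(CF)` (and the square root of
#'   each per-variable term). Default `FALSE`.
#' @return An object of class `cost_breakdown`: list with `cf`,
#'   `per_variable` (named vector), `I` and `K`.
#' @examples
#' e <- matrix(c(10, 10), 1, 2, dimnames = list(NULL, c("a", "b")))
#' s <- matrix(c(9, 7), 1, 2, dimnames = list(NULL, c("a", "b")))
#' cost_function(e, s)$cf # (0.01 + 0.09) / 2 = 0.05
#' @export
cost_function <- function(exp_data, sim_data, sqrt_metric = FALSE) {
  exp_data <- as.matrix(exp_data)
  sim_data <- as.matrix(sim_data)
  if (!identical(dim(exp_data), dim(sim_data))) {
    stop("experimental and simulated data must have identical shape")
  }
  if (!is.null(colnames(exp_data)) && !is.null(colnames(sim_data))) {
    sim_data <- sim_data[, colnames(exp_data), drop = FALSE]
  }
  if (any(exp_data == 0)) stop("experimental value of zero: relative error ",
                               "undefined")
  rel2 <- ((exp_data - sim_data) / exp_data)^2
  per_variable <- colMeans(rel2)
  cf <- mean(per_variable)
  if (sqrt_metric) {
    per_variable <- sqrt(per_variable)
    cf <- sqrt(cf)
  }
  structure(list(cf = cf, per_variable = per_variable,
                 I = ncol(exp_data), K = nrow(exp_data)),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown> cf = ", format(x$cf, digits = 6), " (", x$I,
      " variables x ", x$K, " levels)\n", sep = "")
  invisible(x)
}

#' Optimization bounds around nominal values
#'
#' Sets each parameter's optimization bounds as a symmetric relative
#' interval around its nominal value: `general_pct`% for parameters directly
#' tied to a physiological measure and the wider `unlinked_pct`% for
#' weighting parameters without a direct physiological counterpart. Bounds
#' always reference the nominal values, never the current (warm-started)
#' values. Explicit per-parameter overrides are applied last.
#'
#' @param params a [parameter_set()].
#' @param general_pct half-width (%) for measure-linked parameters
#'   (default 30).
#' @param unlinked_pct half-width (%) for unlinked parameters (default 50).
#' @param overrides optional named list of `c(lower, upper)` pairs.
#' @return The `parameter_set` with updated `lower`/`upper` columns.
#' @export
make_bounds <- function(params, general_pct = 30, unlinked_pct = 50,
                        overrides = NULL) {
  pct <- ifelse(params$measure_linked, general_pct, unlinked_pct) / 100
  if (any(params$nominal == 0)) {
    stop("cannot form relative bounds around zero nominal for: ",
         paste(params$name[params$nominal == 0], collapse = ", "))
  }
  params$lower <- params$nominal - abs(params$nominal) * pct
  params$upper <- params$nominal + abs(params$nominal) * pct
  for (nm in names(overrides)) {
    b <- overrides[[nm]]
    if (length(b) != 2L || b[1L] >= b[2L]) {
      stop("invalid bound override for ", nm, ": lower must be < upper")
    }
    i <- param_index(params, nm)
    params$lower[i] <- b[1L]
    params$upper[i] <- b[2L]
  }
  params$value <- pmin(pmax(params$value, params$lower), params$upper)
  validate_parameter_set(params)
  params
}

#' CMA-ES optimizer settings
#'
#' @param sigma0 initial step size in normalized (unit box) coordinates.
#' @param popsize offspring per generation; default `4 + floor(3 log d)`,
#'   resolved at run time from the search dimension.
#' @param max_evaluations objective evaluation budget; default `500 * d`.
#' @param tol_cf stop when the best cost falls below this value.
#' @param seed integer seed; recorded in every stage log.
#' @return A list of class `optimizer_settings`.
#' @export
optimizer_settings <- function(sigma0 = 0.3, popsize = NULL,
                               max_evaluations = NULL, tol_cf = 1e-9,
                               seed = 1L) {
  stopifnot(sigma0 > 0, sigma0 <= 1)
  structure(list(sigma0 = sigma0, popsize = popsize,
                 max_evaluations = max_evaluations, tol_cf = tol_cf,
                 seed = as.integer(seed)),
            class = "optimizer_settings")
}
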