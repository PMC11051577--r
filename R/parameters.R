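#' Parameter sets
#'
#' A `parameter_set` is the object being fitted and tracked: an ordered
#' collection of named model parameters, each carrying a nominal (reference)
#' value, a current value, a role, absolute optimization bounds and a flag
#' saying whether the parameter is directly tied to a physiological measure
#' (which decides its default bound width, see [make_bounds()]).
#'
#' Roles partition the parameters into five groups: `time_constant`,
#' `conversion`, `covariate`, `initial_value` and `gain_threshold`. Only
#' `gain_threshold` parameters are eligible for optimization; the others are
#' either structural constants or are assigned from measurements during
#' standardization.
#'
#' @param name character vector of unique parameter names.
#' @param nominal numeric vector of reference values (model units).
#' @param role character vector, each one of the five roles.
#' @param measure_linked logical; `TRUE` when the parameter corresponds to a
#'   directly measurable physiological quantity.
#' @param value current values; defaults to `nominal`.
#' @param lower,upper absolute bounds; default to the `make_bounds()` rule
#'   (30% around nominal when measure-linked, 50% otherwise).
#' @return An object of class `parameter_set`: a data frame with columns
#'   `name`, `role`, `nominal`, `value`, `lower`, `upper`, `measure_linked`.
#' @seealso [cr_surrogate_parameters()] for the demonstration model's table.
#' @export
parameter_set <- function(name, nominal, role, measure_linked = FALSE,
                          value = nominal, lower = NULL, upper = NULL) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("parameter names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  roles <- c("time_constant", "conversion", "covariate", "initial_value",
             "gain_threshold")
  role <- as.character(role)
  bad <- setdiff(unique(role), roles)
  if (length(bad)) stop("unknown parameter role(s): ", paste(bad, collapse = ", "))
  n <- length(name)
  measure_linked <- rep_len(as.logical(measure_linked), n)
  nominal <- rep_len(as.numeric(nominal), n)
  value <- rep_len(as.numeric(value), n)
  if (is.null(lower) || is.null(upper)) {
    pct <- ifelse(measure_linked, 0.30, 0.50)
    lo <- nominal - abs(nominal) * pct
    hi <- nominal + abs(nominal) * pct
    if (is.null(lower)) lower <- lo
    if (is.null(upper)) upper <- hi
  }
  ps <- data.frame(name = name, role = rep_len(role, n), nominal = nominal,
                   value = value, lower = as.numeric(rep_len(lower, n)),
                   upper = as.numeric(rep_len(upper, n)),
                   measure_linked = measure_linked,
                   stringsAsFactors = FALSE)
  class(ps) <- c("parameter_set", "data.frame")
  validate_parameter_set(ps)
  ps
}

validate_parameter_set <- function(ps) {
  stopifnot(is.data.frame(ps))
  if (any(ps$lower >= ps$upper)) {
    stop("degenerate bounds (lower >= upper) for: ",
         paste(ps$name[ps$lower >= ps$upper], collapse = ", "))
  }
  out <- ps$value < ps$lower | ps$value > ps$upper
  if (any(out)) {
    stop("parameter value outside bounds for: ",
         paste(ps$name[out], collapse = ", "))
  }
  invisible(ps)
}

param_index <- function(ps, names) {
  i <- match(names, ps$name)
  if (anyNA(i)) stop("unknown parameter name(s): ",
                     paste(names[is.na(i)], collapse = ", "))
  i
}

#' Get or set current parameter values
#'
#' @param ps a [parameter_set()].
#' @param names parameter names; default all.
#' @return `param_values()` returns a named numeric vector of current values.
#' @export
param_values <- function(ps, names = ps$name) {
  i <- param_index(ps, names)
  stats::setNames(ps$value[i], ps$name[i])
}

#' @rdname param_values
#' @param values named numeric vector, or unnamed vector aligned with `names`.
#' @param clip if `TRUE`, values are clipped into the parameter bounds instead
#'   of erroring when outside.
#' @return `set_param_values()` returns the updated `parameter_set`.
#' @export
set_param_values <- function(ps, values, names = NULL, clip = FALSE) {
  if (is.null(names)) {
    if (is.null(base::names(values))) stop("values must be named")
    names <- base::names(values)
  }
  i <- param_index(ps, names)
  v <- as.numeric(values)
  if (clip) v <- pmin(pmax(v, ps$lower[i]), ps$upper[i])
  ps$value[i] <- v
  validate_parameter_set(ps)
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", nrow(x), " parameters\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
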