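#' Classify parameters by role
#'
#' Partitions a parameter set into the five role groups. Only the gain and
#' threshold group is eligible for optimization downstream; time constants,
#' conversion factors, covariates and initial values are either structural
#' or assigned from measurements during standardization.
#'
#' @param params a [parameter_set()].
#' @return Named list with one character vector per role (all five roles
#'   always present, possibly empty).
#' @export
classify_by_role <- function(params) {
  roles <- c("time_constant", "conversion", "covariate", "initial_value",
             "gain_threshold")
  out <- lapply(roles, function(r) params$name[params$role == r])
  names(out) <- roles
  out
}

#' Relative sensitivity matrix of the model outputs
#'
#' Perturbs each candidate parameter over `n_points` uniformly spaced
#' relative variations in `±variation_pct`% of its current value, simulates
#' the model at the given stimulus levels, and records, for every
#' (variable, stimulus-level) pair, the least-squares slope of the
#' normalized output change (dy/y0) against the normalized parameter change
#' (dtheta/theta0) — a dimensionless relative sensitivity. Each row also
#' carries an error-contribution weight: the absolute relative error of that
#' variable/level at the current parameter values with respect to the
#' experimental data.
#'
#' @param model a model object (see [cr_surrogate()]).
#' @param params a [parameter_set()].
#' @param stimuli data frame with columns `vo2`, `vco2`: the stimulus levels
#'   at which sensitivities are probed (typically rest, an intermediate
#'   level, and the anaerobic threshold).
#' @param exp_data matrix `nrow(stimuli) x 10` of experimental values used
#'   for the error-contribution weights, or `NULL` for unit weights.
#' @param candidates parameter names to probe; defaults to the
#'   gain-and-threshold role group.
#' @param variation_pct half-width of the relative perturbation range in
#'   percent (default 5).
#' @param n_points number of uniformly spaced perturbations (default 5).
#' @return An object of class `sensitivity_matrix`: a list with the entries
#'   matrix `S` (rows = variable x level, columns = candidates), the
#'   `row_weights`, and row bookkeeping (`row_variable`, `row_level`).
#' @export
build_sensitivity_matrix <- function(model, params, stimuli, exp_data = NULL,
                                     candidates = NULL, variation_pct = 5,
                                     n_points = 5L) {
  if (is.null(candidates)) {
    candidates <- classify_by_role(params)$gain_threshold
  }
  if (!length(candidates)) stop("no candidate parameters to probe")
  k <- nrow(stimuli)
  vars <- model$variables
  base_values <- param_values(params)
  y0 <- model$simulate(base_values, stimuli$vo2, stimuli$vco2)
  deltas <- seq(-variation_pct, variation_pct, length.out = n_points) / 100
  n_rows <- length(vars) * k
  S <- matrix(0, n_rows, length(candidates),
              dimnames = list(NULL, candidates))
  for (p in candidates) {
    theta0 <- base_values[[p]]
    if (theta0 == 0) stop("cannot form relative variation of zero-valued ",
                          "parameter ", p)
    rel <- matrix(0, n_rows, n_points)
    for (j in seq_along(deltas)) {
      v <- base_values
      v[[p]] <- theta0 * (1 + deltas[j])
      yj <- model$simulate(v, stimuli$vo2, stimuli$vco2)
      rel[, j] <- as.vector((yj - y0) / y0)   # column-major: level fastest
    }
    ## least-squares slope through the perturbation design (zero-mean deltas)
    S[, p] <- as.vector(rel %*% deltas) / sum(deltas^2)
  }
  row_variable <- rep(vars, each = k)
  row_level <- rep(seq_len(k), length(vars))
  if (is.null(exp_data)) {
    w <- rep(1, n_rows)
  } else {
    exp_data <- exp_data[, vars, drop = FALSE]
    w <- abs(as.vector((exp_data - y0) / exp_data))
  }
  rownames(S) <- paste0(row_variable, "@", row_level)
  structure(list(S = S, row_weights = w, row_variable = row_variable,
                 row_level = row_level, variables = vars),
            class = "sensitivity_matrix")
}

total_sensitivity <- function(sm) {
  w <- sm$row_weights
  if (all(w == 0)) w <- rep(1, length(w))
  w <- w / sum(w)
  sqrt(as.vector(w %*% sm$S^2))
}

collinearity_index <- function(S_sub) {
  norms <- sqrt(colSums(S_sub^2))
  Sn <- sweep(S_sub, 2, norms, "/")
  1 / min(svd(Sn, nu = 0, nv = 0)$d)
}

#' Select the base optimization set by sensitivity and identifiability
#'
#' Greedy forward selection of the parameters optimized jointly against the
#' full cost: at each step, the remaining candidate with the highest total
#' sensitivity (error-weighted root-mean-square of its sensitivity column)
#' is added if the collinearity index of the column-normalized selected
#' submatrix (1/smallest singular value) stays at or below the threshold.
#' Selection stops at `target_size` or when no candidate qualifies. Ties in
#' total sensitivity are broken by name order, so the result is invariant to
#' candidate ordering.
#'
#' @param sm a [build_sensitivity_matrix()] result.
#' @param target_size number of parameters to select (default 8).
#' @param collinearity_threshold maximum admissible collinearity index
#'   (default 15, the conventional identifiability cutoff).
#' @return Character vector of selected names, with a `diagnostics`
#'   attribute (data frame: name, total sensitivity, collinearity index at
#'   inclusion, selected flag).
#' @export
select_base_set <- function(sm, target_size = 8L,
                            collinearity_threshold = 15) {
  ts <- total_sensitivity(sm)
  names(ts) <- colnames(sm$S)
  if (all(ts == 0)) stop("all candidate sensitivities are zero; nothing ",
                         "is identifiable")
  if (target_size > ncol(sm$S)) stop("target_size exceeds candidate count")
  ord <- order(-ts, names(ts))
  selected <- character(0)
  coll_at <- numeric(0)
  for (p in names(ts)[ord]) {
    if (length(selected) >= target_size) break
    if (ts[[p]] <= 0) next
    idx <- c(selected, p)
    ci <- collinearity_index(sm$S[, idx, drop = FALSE])
    if (ci <= collinearity_threshold) {
      selected <- idx
      coll_at <- c(coll_at, ci)
    }
  }
  if (!length(selected)) stop("no identifiable candidate under the ",
                              "collinearity threshold")
  diagnostics <- data.frame(name = names(ts)[ord],
                            total_sensitivity = ts[ord],
                            row.names = NULL)
  diagnostics$collinearity_at_inclusion <-
    coll_at[match(diagnostics$name, selected)]
  diagnostics$selected <- diagnostics$name %in% selected
  attr(selected, "diagnostics") <- diagnostics
  selected
}

#' Select variable-specific refinement sets
#'
#' For each output variable, picks the non-base parameter with the best
#' relative sensitivity for that variable — the one maximizing the ratio of
#' its sensitivity to the variable against its strongest sensitivity to any
#' other variable — provided that ratio reaches `dominance_ratio`, i.e. the
#' parameter has no significant cross-effect on the other variables.
#' Variables may map to empty sets.
#'
#' @inheritParams select_base_set
#' @param base_set names already selected for the base set (excluded here).
#' @param dominance_ratio minimum within/cross sensitivity ratio (> 1,
#'   default 2).
#' @return Named list mapping each variable to a character vector (length 0
#'   or 1) of parameter names.
#' @export
select_specific_sets <- function(sm, base_set, dominance_ratio = 2) {
  stopifnot(dominance_ratio > 1)
  vars <- sm$variables
  pool <- setdiff(colnames(sm$S), base_set)
  ## per-variable RMS sensitivity of each candidate
  per_var <- t(vapply(vars, function(v) {
    rows <- sm$row_variable == v
    sqrt(colMeans(sm$S[rows, , drop = FALSE]^2))
  }, numeric(ncol(sm$S))))
  dimnames(per_var) <- list(vars, colnames(sm$S))
  out <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) {
    out[[v]] <- character(0)
    if (!length(pool)) next
    ratio <- vapply(pool, function(p) {
      own <- per_var[v, p]
      cross <- max(per_var[setdiff(vars, v), p])
      if (own == 0) return(0)
      if (cross == 0) return(Inf)
      own / cross
    }, 0)
    best <- pool[order(-ratio, pool)][1L]
    if (ratio[[best]] >= dominance_ratio) out[[v]] <- best
  }
  out
}

#' Full parameter selection for one record
#'
#' Convenience wrapper running the whole selection step: probes the
#' gain-and-threshold parameters at three stimulus levels (rest at
#' V̇CO2 = 0.3 L/min, the midpoint to the anaerobic threshold, and the
#' threshold itself), builds the relative sensitivity matrix weighted by the
#' record's current-error contribution, and returns the base and
#' variable-specific sets.
#'
#' @inheritParams build_sensitivity_matrix
#' @param record a [longitudinal_record()] providing the stimulus range and
#'   the experimental weights (observations interpolated onto the three
#'   probe levels).
#' @inheritParams select_base_set
#' @inheritParams select_specific_sets
#' @param rer respiratory exchange ratio used to map V̇CO2 to V̇O2 at the
#'   probe levels.
#' @return An object of class `selection_result`: list with `base_set`,
#'   `specific_sets`, `diagnostics`, and the `sensitivity` matrix object.
#' @export
select_parameters <- function(model, params, record, target_size = 8L,
                              collinearity_threshold = 15,
                              dominance_ratio = 2, variation_pct = 5,
                              n_points = 5L, rer = 0.9) {
  at <- record$at_vco2 %||% max(record$stimulus$vco2)
  vco2 <- c(0.3, (0.3 + at) / 2, at)
  stimuli <- data.frame(vo2 = vco2 / rer, vco2 = vco2)
  exp_data <- NULL
  if (!is.null(record$observations)) {
    exp_data <- apply(record$observations, 2, function(y) {
      stats::approx(record$stimulus$vco2, y, xout = vco2, rule = 2)$y
    })
  }
  sm <- build_sensitivity_matrix(model, params, stimuli, exp_data = exp_data,
                                 variation_pct = variation_pct,
                                 n_points = n_points)
  base <- select_base_set(sm, target_size = target_size,
                          collinearity_threshold = collinearity_threshold)
  specific <- select_specific_sets(sm, base,
                                   dominance_ratio = dominance_ratio)
  structure(list(base_set = as.character(base),
                 specific_sets = specific,
                 diagnostics = attr(base, "diagnostics"),
                 sensitivity = sm),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n  base set: ",
      paste(x$base_set, collapse = ", "), "\n", sep = "")
  sp <- Filter(length, x$specific_sets)
  if (length(sp)) {
    cat("  specific sets:\n")
    for (v in names(sp)) cat("    ", v, ": ", paste(sp[[v]], collapse = ", "),
                             "\n", sep = "")
  }
  invisible(x)
}

#' Export selection diagnostics
#'
#' Writes the per-parameter selection diagnostics (total sensitivity,
#' collinearity index at inclusion, and which set each parameter was
#' selected for) as a CSV table.
#'
#' @param selection a [select_parameters()] result.
#' @param path output CSV path.
#' @return Invisibly, the exported data frame.
#' @export
export_selection_diagnostics <- function(selection, path) {
  d <- selection$diagnostics
  spec <- unlist(lapply(names(selection$specific_sets), function(v) {
    stats::setNames(rep(v, length(selection$specific_sets[[v]])),
                    selection$specific_sets[[v]])
  }))
  d$selected_for <- ifelse(d$name %in% selection$base_set, "base",
                           ifelse(d$name %in% names(spec),
                                  unname(spec[d$name]), ""))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}
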