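#' Resample a parameter trajectory onto a uniform time grid
#'
#' ARX trend models require a constant sampling time, but longitudinal
#' records are irregularly spaced. This linearly interpolates a parameter's
#' fitted-value trajectory and the factor inputs onto the grid
#' `0, ts, 2 ts, ...` up to the last record time. When the total span is a
#' multiple of `ts` the endpoints are preserved exactly.
#'
#' @param times record times (years), strictly increasing, first 0.
#' @param values fitted parameter values at `times`.
#' @param inputs data frame or matrix of factor inputs aligned with `times`
#'   (one column per input), or `NULL`.
#' @param ts sampling time in years, within `[0.1, 0.4]`.
#' @return List with `time` (the uniform grid), `y` (resampled values) and
#'   `U` (resampled input matrix or `NULL`).
#' @export
resample_uniform <- function(times, values, inputs = NULL, ts) {
  if (ts < 0.1 || ts > 0.4) {
    stop("sampling time must lie in [0.1, 0.4] years (got ", ts, ")")
  }
  if (length(times) < 2L) stop("need at least 2 records to resample")
  stopifnot(!is.unsorted(times, strictly = TRUE), length(values) ==
              length(times))
  span <- times[length(times)] - times[1L]
  n_steps <- floor(span / ts + 1e-9)
  grid <- times[1L] + ts * seq.int(0L, n_steps)
  y <- stats::approx(times, values, xout = grid, rule = 2)$y
  ## exact endpoint preservation against float drift
  y[1L] <- values[1L]
  if (abs(grid[length(grid)] - times[length(times)]) < 1e-9) {
    y[length(y)] <- values[length(values)]
  }
  U <- NULL
  if (!is.null(inputs)) {
    inputs <- as.matrix(inputs)
    stopifnot(nrow(inputs) == length(times))
    U <- apply(inputs, 2, function(u) {
      stats::approx(times, u, xout = grid, rule = 2)$y
    })
    U <- matrix(U, nrow = length(grid),
                dimnames = list(NULL, colnames(inputs)))
  }
  list(time = grid, y = y, U = U)
}

#' Akaike's Information Criterion for trend-model order selection
#'
#' `AIC = ln(V) + 2 d / N`, where `V` is the loss function (normalized sum
#' of squared one-step prediction errors), `d` the number of estimated
#' coefficients, and `N` the number of samples used for estimation.
#'
#' @param loss_v loss function value (> 0; zero is clamped to `floor` with
#'   a warning).
#' @param d number of model coefficients.
#' @param n_samples number of estimation samples.
#' @param floor clamp for a zero loss (default `1e-12`).
#' @return The AIC value.
#' @export
aic_score <- function(loss_v, d, n_samples, floor = 1e-12) {
  stopifnot(loss_v >= 0, n_samples >= 1)
  if (loss_v < floor) {
    warning("loss function at or below floor; clamped to ", floor)
    loss_v <- floor
  }
  log(loss_v) + 2 * d / n_samples
}

#' Least-squares fit of an ARX trend model
#'
#' Fits the autoregressive-with-exogenous-inputs structure
#' `A(q) y(n) = sum_i B_i(q) u_i(n) + e(n)` by ordinary least squares on its
#' regression form, with `A(q) = 1 + a_1 q^-1 + ... + a_na q^-na` and
#' `B_i(q) = b_{i,0} + b_{i,1} q^-1 + ... + b_{i,nb_i - 1} q^-(nb_i - 1)`
#' (all input delays zero, no intercept). The trend models are small MISO
#' models of a fitted parameter's value driven by time and lifestyle
#' factors.
#'
#' @param y uniformly sampled output series.
#' @param U input matrix (`length(y)` rows, one column per input), or
#'   `NULL` for a purely autoregressive model.
#' @param na order of `A` (number of autoregressive coefficients, >= 0).
#' @param nb integer vector of `B` orders per input (each >= 0; an input
#'   with order 0 is excluded). Recycled to `ncol(U)`.
#' @param ts sampling time of the series (years), stored for prediction.
#' @return An object of class `arx_model`: orders, coefficient vectors
#'   `coeffs_a` (a_1..a_na) and `coeffs_b` (list per input), `fit_pct`
#'   (goodness of fit, % of output variation explained on the modeled
#'   samples), `loss_v` (mean squared one-step residual), `aic`, `d`,
#'   `n_samples`, plus the residuals.
#' @export
fit_arx <- function(y, U = NULL, na = 1L, nb = 0L, ts = NA_real_) {
  n <- length(y)
  n_in <- if (is.null(U)) 0L else ncol(U)
  if (n_in > 0L) {
    U <- as.matrix(U)
    stopifnot(nrow(U) == n)
  }
  nb <- rep_len(as.integer(nb), max(n_in, 1L))
  if (n_in == 0L) nb <- integer(0)
  na <- as.integer(na)
  d <- na + sum(nb)
  if (d == 0L) stop("model has no coefficients (na = 0 and all nb = 0)")
  max_lag <- max(na, if (length(nb)) max(nb) - 1L else 0L)
  rows <- seq.int(max_lag + 1L, n)
  n_samples <- length(rows)
  if (n_samples <= d) {
    stop("not enough samples (", n_samples, ") for ", d, " coefficients")
  }
  reg <- matrix(0, n_samples, d)
  cn <- character(d)
  col <- 0L
  for (j in seq_len(na)) {
    col <- col + 1L
    reg[, col] <- -y[rows - j]
    cn[col] <- paste0("a", j)
  }
  for (i in seq_len(n_in)) {
    for (j in seq_len(nb[i])) {
      col <- col + 1L
      reg[, col] <- U[rows - (j - 1L), i]
      cn[col] <- paste0("b", i, ".", j - 1L)
    }
  }
  colnames(reg) <- cn
  qr_reg <- qr(reg)
  if (qr_reg$rank < d) {
    stop("singular ARX regressor matrix (rank ", qr_reg$rank, " < ", d, ")")
  }
  theta <- qr.coef(qr_reg, y[rows])
  yhat <- as.vector(reg %*% theta)
  e <- y[rows] - yhat
  loss_v <- mean(e^2)
  denom <- sqrt(sum((y[rows] - mean(y[rows]))^2))
  fit_pct <- if (denom > 0) 100 * (1 - sqrt(sum(e^2)) / denom) else
    if (sum(e^2) < 1e-20) 100 else -Inf
  coeffs_a <- if (na > 0L) unname(theta[seq_len(na)]) else numeric(0)
  coeffs_b <- vector("list", n_in)
  col <- na
  for (i in seq_len(n_in)) {
    coeffs_b[[i]] <- if (nb[i] > 0L) {
      unname(theta[col + seq_len(nb[i])])
    } else numeric(0)
    col <- col + nb[i]
  }
  names(coeffs_b) <- colnames(U)
  structure(list(na = na, nb = nb, delays = rep(0L, n_in),
                 coeffs_a = coeffs_a, coeffs_b = coeffs_b, ts = ts,
                 fit_pct = fit_pct, loss_v = loss_v,
                 aic = aic_score(loss_v, d, n_samples), d = d,
                 n_samples = n_samples, residuals = e),
            class = "arx_model")
}

#' @export
print.arx_model <- function(x, ...) {
  cat("<arx_model> na = ", x$na, ", nb = (", paste(x$nb, collapse = ","),
      "), ts = ", x$ts, " yr, fit ", round(x$fit_pct, 1), "%, AIC ",
      round(x$aic, 3), "\n", sep = "")
  invisible(x)
}

## One-step-ahead simulation of a fitted ARX model along its own sampling
## grid: y(n) = -sum a_j y(n-j) + sum_i sum_l b_{i,l} u_i(n-l).
arx_step <- function(model, y_hist, u_now_hist) {
  out <- 0
  for (j in seq_len(model$na)) {
    out <- out - model$coeffs_a[j] * y_hist[length(y_hist) - j + 1L]
  }
  for (i in seq_along(model$coeffs_b)) {
    bi <- model$coeffs_b[[i]]
    for (l in seq_along(bi)) {
      out <- out + bi[l] * u_now_hist[nrow(u_now_hist) - l + 1L, i]
    }
  }
  out
}

#' Exhaustive AIC-based selection of the ARX trend model
#'
#' Searches the grid of sampling times and polynomial orders for the
#' minimum-AIC ARX model of one parameter trajectory: sampling times from
#' `ts_grid` (within the admissible `[0.1, 0.4]` year range), `na` from 0 to
#' `max_order`, and each input's `nb` from 0 to `max_order`, keeping only
#' structures whose coefficient count stays below the number of modeled
#' samples and whose regressors are full rank. Ties in AIC are broken by
#' the smaller coefficient count, then the smaller sampling time.
#'
#' @param times,values,inputs as in [resample_uniform()].
#' @param ts_grid candidate sampling times (years).
#' @param max_order order cap for `na` and each `nb` (default 3, keeping
#'   the coefficient count below the sample count of short series).
#' @return The best `arx_model` (with attribute `resampled`: the winning
#'   uniform series), or `NULL` when no admissible structure exists.
#' @export
select_arx_model <- function(times, values, inputs = NULL,
                             ts_grid = c(0.1, 0.2, 0.3, 0.4),
                             max_order = 3L) {
  best <- NULL
  n_in <- if (is.null(inputs)) 0L else ncol(as.matrix(inputs))
  nb_grid <- if (n_in > 0L) {
    as.matrix(expand.grid(rep(list(0:max_order), n_in)))
  } else {
    matrix(integer(0), 1L, 0L)
  }
  for (ts in ts_grid) {
    rs <- resample_uniform(times, values, inputs, ts)
    n <- length(rs$y)
    for (na in 0:max_order) {
      for (r in seq_len(nrow(nb_grid))) {
        nb <- as.integer(nb_grid[r, ])
        d <- na + sum(nb)
        if (d == 0L) next
        max_lag <- max(na, if (length(nb)) max(nb) - 1L else 0L)
        if (n - max_lag <= d) next      # d must stay below sample count
        fit <- tryCatch(
          suppressWarnings(fit_arx(rs$y, rs$U, na, nb, ts = ts)),
          error = function(e) NULL)
        if (is.null(fit)) next
        if (is.null(best) ||
            fit$aic < best$aic - 1e-12 ||
            (abs(fit$aic - best$aic) <= 1e-12 &&
               (fit$d < best$d ||
                  (fit$d == best$d && fit$ts < best$ts)))) {
          attr(fit, "resampled") <- rs
          best <- fit
        }
      }
    }
  }
  best
}

#' Predict fitted parameter values at the next record
#'
#' Implements the dynamic-parameter step: for every tracked parameter, the
#' fitted-value trajectory over past records is examined; parameters that
#' never varied significantly during optimization keep their previous value
#' (`not_modeled`). For the rest, the best ARX trend model
#' ([select_arx_model()]) driven by time, physical activity, sleep and the
#' anaerobic threshold is identified and stepped forward to the next record
#' time. Physiological-justification gates then screen each prediction:
#' models with goodness of fit below `min_fit_pct` are discarded
#' (`rejected_gof`), as are predictions changing sign against the previous
#' value (`rejected_sign`) or moving by more than half the recorded value
#' range (`rejected_range`); discarded parameters fall back to the previous
#' record's value.
#'
#' Except for time, which advances by `horizon`, the future inputs are
#' taken equal to the previous record's inputs.
#'
#' @param series a [fit_longitudinal()] result (needs >= 2 records).
#' @param horizon years from the last record to the predicted one.
#' @param min_fit_pct goodness-of-fit gate in percent (default 60).
#' @param modification_tol relative change between consecutive fits above
#'   which a parameter counts as modified (default 0.005).
#' @param range_gate_factor admissible change as a fraction of the recorded
#'   value range (default 0.5; when the range is degenerate the same
#'   fraction of the previous absolute value is used).
#' @param ts_grid,max_order passed to [select_arx_model()].
#' @param names parameters to consider; default the tracked base and
#'   specific sets of the series' selection.
#' @return An object of class `prediction_outcomes`: a list with one entry
#'   per parameter — `name`, `status` (`accepted`, `rejected_gof`,
#'   `rejected_sign`, `rejected_range`, `not_modeled`), `predicted_value`,
#'   `fallback_value`, `value` (the one to use downstream), and `model`
#'   (the `arx_model` or `NULL`) — plus attributes `horizon` and `time`.
#' @export
predict_next_parameters <- function(series, horizon = 1,
                                    min_fit_pct = 60,
                                    modification_tol = 0.005,
                                    range_gate_factor = 0.5,
                                    ts_grid = c(0.1, 0.2, 0.3, 0.4),
                                    max_order = 3L, names = NULL) {
  fits <- series$fits
  if (length(fits) < 2L) {
    stop("need at least two fitted records to model parameter trends")
  }
  if (is.null(names)) {
    names <- unique(c(series$selection$base_set,
                      unlist(series$selection$specific_sets)))
  }
  times <- vapply(fits, `[[`, 0, "time_years")
  factors <- series$factors
  inputs <- cbind(time = factors$time, activity = factors$activity,
                  sleep = factors$sleep, at_vco2 = factors$at_vco2)
  keep <- colSums(is.na(inputs)) == 0L
  inputs <- inputs[, keep, drop = FALSE]
  traj <- vapply(fits, function(f) param_values(f$params, names),
                 numeric(length(names)))
  traj <- matrix(traj, nrow = length(names),
                 dimnames = list(names, NULL))
  outcomes <- vector("list", length(names))
  base::names(outcomes) <- names
  t_next <- times[length(times)] + horizon
  for (p in names) {
    y <- traj[p, ]
    prev <- y[length(y)]
    rel_change <- abs(diff(y)) / pmax(abs(y[-length(y)]), 1e-300)
    modified <- rel_change > modification_tol
    outcome <- list(name = p, status = "not_modeled",
                    predicted_value = NA_real_, fallback_value = prev,
                    value = prev, model = NULL)
    ## model only parameters optimized to new values at least twice
    if (sum(modified) >= 2L) {
      fit <- select_arx_model(times, y, inputs, ts_grid = ts_grid,
                              max_order = max_order)
      if (!is.null(fit)) {
        pred <- arx_forecast(fit, times, y, inputs, t_next)
        outcome$model <- fit
        outcome$predicted_value <- pred
        rng <- diff(range(y))
        gate_span <- if (rng > 0) range_gate_factor * rng else
          range_gate_factor * abs(prev)
        if (fit$fit_pct < min_fit_pct) {
          outcome$status <- "rejected_gof"
        } else if (sign(pred) != sign(prev)) {
          outcome$status <- "rejected_sign"
        } else if (abs(pred - prev) > gate_span * (1 + 1e-9) + 1e-12) {
          outcome$status <- "rejected_range"
        } else {
          outcome$status <- "accepted"
          outcome$value <- pred
        }
      }
    }
    outcomes[[p]] <- outcome
  }
  structure(outcomes, class = "prediction_outcomes", horizon = horizon,
            time = t_next)
}

## Steps a selected ARX model forward from the end of the observed
## trajectory to the target time on its own sampling grid. Future inputs
## hold the last record's values; time advances along the grid.
arx_forecast <- function(model, times, values, inputs, t_target) {
  ts <- model$ts
  rs <- attr(model, "resampled")
  y <- rs$y
  U <- rs$U
  t_grid <- rs$time
  n_ahead <- max(1L, as.integer(round((t_target - t_grid[length(t_grid)]) / ts)))
  for (s in seq_len(n_ahead)) {
    t_new <- t_grid[length(t_grid)] + ts
    if (!is.null(U)) {
      u_new <- U[nrow(U), , drop = FALSE]
      if ("time" %in% colnames(U)) u_new[1L, "time"] <- t_new
      U <- rbind(U, u_new)
    }
    y <- c(y, 0)                        # placeholder, filled by arx_step
    y[length(y)] <- arx_step(model, y[-length(y)],
                             if (is.null(U)) matrix(0, 1, 0) else U)
    t_grid <- c(t_grid, t_new)
  }
  y[length(y)]
}

#' @export
print.prediction_outcomes <- function(x, ...) {
  cat("<prediction_outcomes> at t = ", attr(x, "time"), " yr\n", sep = "")
  for (o in x) {
    cat(sprintf("  %-8s %-14s value %.6g", o$name, o$status, o$value))
    if (!is.na(o$predicted_value)) {
      cat(sprintf(" (predicted %.6g)", o$predicted_value))
    }
    cat("\n")
  }
  invisible(x)
}

#' Export a per-parameter trend report
#'
#' Writes the trend-modeling outcome per parameter (status, selected
#' sampling time and orders, fit quality, AIC, predicted and fallback
#' values) as CSV, with model coefficients in a companion JSON file.
#'
#' @param outcomes a [predict_next_parameters()] result.
#' @param csv_path output CSV path.
#' @param json_path optional companion JSON path for the coefficients.
#' @return Invisibly, the report data frame.
#' @export
export_trend_report <- function(outcomes, csv_path, json_path = NULL) {
  rows <- lapply(outcomes, function(o) {
    m <- o$model
    data.frame(name = o$name, status = o$status,
               ts = if (is.null(m)) NA_real_ else m$ts,
               na = if (is.null(m)) NA_integer_ else m$na,
               nb = if (is.null(m)) "" else paste(m$nb, collapse = ";"),
               fit_pct = if (is.null(m)) NA_real_ else m$fit_pct,
               aic = if (is.null(m)) NA_real_ else m$aic,
               predicted = o$predicted_value, fallback = o$fallback_value,
               value = o$value)
  })
  report <- do.call(rbind, rows)
  utils::write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    coeffs <- lapply(outcomes, function(o) {
      if (is.null(o$model)) return(NULL)
      list(coeffs_a = o$model$coeffs_a, coeffs_b = o$model$coeffs_b,
           ts = o$model$ts)
    })
    jsonlite::write_json(coeffs, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(report)
}
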