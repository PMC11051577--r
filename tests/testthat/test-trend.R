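test_that("uniform resampling interpolates linearly and keeps endpoints", {
  rs <- resample_uniform(c(0, 0.4), c(1, 2), ts = 0.2)
  expect_equal(rs$y, c(1, 1.5, 2))     # linear midpoint
  expect_identical(rs$y[c(1, 3)], c(1, 2))

  ## constant series stays constant; inputs resampled alongside
  rs2 <- resample_uniform(c(0, 1.2), c(3, 3),
                          inputs = cbind(u = c(5, 5)), ts = 0.3)
  expect_true(all(rs2$y == 3))
  expect_true(all(rs2$U[, "u"] == 5))
  expect_equal(rs2$time, seq(0, 1.2, by = 0.3))

  expect_error(resample_uniform(c(0, 1), c(1, 2), ts = 0.5), "0.4")
  expect_error(resample_uniform(c(0, 1), c(1, 2), ts = 0.05), "0.1")
})

test_that("ARX least squares recovers noiseless generators exactly", {
  set.seed(10)
  u <- stats::runif(30)
  y <- numeric(30)
  for (n in 2:30) y[n] <- 0.8 * y[n - 1] + 0.5 * u[n]
  fit <- suppressWarnings(fit_arx(y, cbind(u = u), na = 1, nb = 1, ts = 0.1))
  expect_equal(fit$coeffs_a[1], -0.8, tolerance = 1e-8)
  expect_equal(fit$coeffs_b$u[1], 0.5, tolerance = 1e-8)
  expect_gt(fit$fit_pct, 99.99)

  ## persistence model on a constant series: a1 = -1, zero residuals
  fitc <- suppressWarnings(fit_arx(rep(4, 8), NULL, na = 1, ts = 0.1))
  expect_equal(fitc$coeffs_a[1], -1)
  expect_equal(max(abs(fitc$residuals)), 0)

  ## residual bookkeeping: loss equals the mean squared residual
  set.seed(11)
  yn <- y + stats::rnorm(30, 0, 0.05)
  fitn <- fit_arx(yn, cbind(u = u), na = 1, nb = 1, ts = 0.1)
  expect_equal(fitn$loss_v, mean(fitn$residuals^2), tolerance = 1e-12)

  ## rank deficiency is an error, not a crash elsewhere
  expect_error(fit_arx(seq_len(10), cbind(a = rep(1, 10), b = rep(2, 10)),
                       na = 0, nb = c(1, 1), ts = 0.1), "singular")
})

test_that("AIC formula and its monotonicity", {
  expect_equal(aic_score(1, 0, 5), 0)
  expect_equal(aic_score(exp(1), 10, 10), 3)
  expect_equal(aic_score(0.01, 2, 10), log(0.01) + 0.4)
  expect_warning(a0 <- aic_score(0, 1, 5), "clamp")
  expect_equal(a0, log(1e-12) + 2 / 5)
  ## increasing in d at fixed loss, increasing in loss at fixed d
  expect_gt(aic_score(0.5, 3, 10), aic_score(0.5, 2, 10))
  expect_gt(aic_score(0.6, 2, 10), aic_score(0.5, 2, 10))
})

test_that("order selection recovers the generator and breaks ties by size", {
  ## trajectory generated by an ARX(1, b_time) law on a 0.2-yr grid
  ts <- 0.2
  tgrid <- seq(0, 2, by = ts)
  y <- numeric(length(tgrid))
  y[1] <- 1
  for (n in 2:length(y)) y[n] <- 0.9 * y[n - 1] + 0.05
  ## observe at the record times only; inputs: time plus a constant factor
  times <- c(0, 0.4, 0.8, 1.2, 1.6, 2)
  vals <- y[match(times, tgrid)]
  inputs <- cbind(time = times, activity = rep(5, 6))
  best <- select_arx_model(times, vals, inputs)
  expect_s3_class(best, "arx_model")
  ## the selected model reproduces the series up to interpolation error
  expect_gt(best$fit_pct, 95)
  expect_lt(best$d, best$n_samples)
})

test_that("a linear drift extrapolates exactly through the trend model", {
  times <- c(0, 1, 2)
  vals <- c(1.0, 1.2, 1.4)
  inputs <- cbind(time = times, activity = c(5, 5, 5), sleep = c(7, 7, 7),
                  at_vco2 = c(1.4, 1.4, 1.4))
  best <- select_arx_model(times, vals, inputs)
  pred <- dynfit:::arx_forecast(best, times, vals, inputs, 3)
  expect_equal(pred, 1.6, tolerance = 1e-6)
})

test_that("justification gates assign exactly one status each", {
  ## build a fit series by hand: three records, controlled trajectories
  mk_series <- function(traj_list, times = c(0, 1, 2)) {
    nm <- names(traj_list)
    fits <- lapply(seq_along(times), function(n) {
      ps <- parameter_set(nm,
                          nominal = vapply(traj_list, `[[`, 0, 1L),
                          role = "gain_threshold",
                          lower = -1e6, upper = 1e6,
                          value = vapply(traj_list, `[[`, 0, n))
      structure(list(params = ps, record_id = paste0("r", n),
                     time_years = times[n]), class = "fit_result")
    })
    structure(list(
      fits = fits,
      selection = list(base_set = nm,
                       specific_sets = stats::setNames(list(), character(0))),
      factors = data.frame(record_id = paste0("r", seq_along(times)),
                           time = times, activity = 5, sleep = 7,
                           at_vco2 = 1.4)),
      class = "fit_series")
  }

  ## constant parameter: never modeled, fallback to the constant
  out <- predict_next_parameters(mk_series(list(const = c(2, 2, 2))),
                                 horizon = 1)
  expect_equal(out$const$status, "not_modeled")
  expect_equal(out$const$value, 2)

  ## clean linear drift: accepted, exact extrapolation
  out2 <- predict_next_parameters(mk_series(list(lin = c(1.0, 1.2, 1.4))),
                                  horizon = 1)
  expect_equal(out2$lin$status, "accepted")
  expect_equal(out2$lin$value, 1.6, tolerance = 1e-6)

  ## sign flip: the trend crosses zero; gated and replaced by previous value
  out3 <- predict_next_parameters(mk_series(list(flip = c(3, 1.7, 0.4))),
                                  horizon = 1)
  expect_equal(out3$flip$status, "rejected_sign")
  expect_equal(out3$flip$value, 0.4)

  ## range gate: accelerating growth extrapolates beyond half the recorded
  ## range and falls back to the previous value
  out4 <- predict_next_parameters(
    mk_series(list(jump = c(0.5, 1, 2))), horizon = 1)
  expect_equal(out4$jump$status, "rejected_range")
  expect_equal(out4$jump$value, 2)

  ## statuses are exhaustive and exclusive
  all_out <- c(out, out2, out3, out4)
  expect_true(all(vapply(all_out, function(o) {
    o$status %in% c("accepted", "rejected_gof", "rejected_sign",
                    "rejected_range", "not_modeled")
  }, NA)))

  ## determinism: identical history yields identical outcomes
  expect_identical(
    predict_next_parameters(mk_series(list(lin = c(1.0, 1.2, 1.4)))),
    predict_next_parameters(mk_series(list(lin = c(1.0, 1.2, 1.4)))))
})

test_that("the goodness-of-fit gate rejects weak trend models", {
  ## a series whose best trend model explains little of the variation:
  ## force a small model on wiggly data via max_order = 1 and one ts
  mk <- function(vals, times) {
    structure(list(
      fits = lapply(seq_along(times), function(n) {
        structure(list(params = parameter_set("p", vals[1],
                                              role = "gain_threshold",
                                              lower = -1e6, upper = 1e6,
                                              value = vals[n]),
                       record_id = paste0("r", n), time_years = times[n]),
                  class = "fit_result")
      }),
      selection = list(base_set = "p",
                       specific_sets = stats::setNames(list(), character(0))),
      factors = data.frame(record_id = paste0("r", seq_along(times)),
                           time = times, activity = 5, sleep = 7,
                           at_vco2 = 1.4)),
      class = "fit_series")
  }
  vals <- 5 + c(0, 1.5, -1.2, 0.3, 1.4, -1.1)
  out <- predict_next_parameters(mk(vals, seq(0, 2, by = 0.4)),
                                 horizon = 0.4, ts_grid = 0.4,
                                 max_order = 1L)
  expect_equal(out$p$status, "rejected_gof")
  expect_equal(out$p$value, vals[6])   # fallback to the previous record
})

test_that("trend report export lists every tracked parameter", {
  times <- c(0, 1, 2)
  series <- structure(list(
    fits = lapply(1:3, function(n) {
      structure(list(params = parameter_set(c("lin", "const"),
                                            nominal = c(1, 2),
                                            role = "gain_threshold",
                                            lower = 0, upper = 10,
                                            value = c(c(1, 1.2, 1.4)[n], 2)),
                     record_id = paste0("r", n), time_years = times[n]),
                class = "fit_result")
    }),
    selection = list(base_set = c("lin", "const"),
                     specific_sets = stats::setNames(list(), character(0))),
    factors = data.frame(record_id = paste0("r", 1:3), time = times,
                         activity = 5, sleep = 7, at_vco2 = 1.4)),
    class = "fit_series")
  out <- predict_next_parameters(series, horizon = 1)
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  rep <- export_trend_report(out, csv, json)
  expect_setequal(rep$name, c("lin", "const"))
  expect_true(file.exists(csv) && file.exists(json))
})
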