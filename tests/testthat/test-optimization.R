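test_that("the relative-error cost matches hand evaluations and identities", {
  e1 <- matrix(10, 1, 1, dimnames = list(NULL, "y"))
  s1 <- matrix(9, 1, 1, dimnames = list(NULL, "y"))
  expect_equal(cost_function(e1, s1)$cf, 0.01)

  e2 <- matrix(c(10, 10), 1, 2, dimnames = list(NULL, c("a", "b")))
  s2 <- matrix(c(9, 7), 1, 2, dimnames = list(NULL, c("a", "b")))
  cb <- cost_function(e2, s2)
  expect_equal(cb$cf, 0.05)            # (0.01 + 0.09) / 2
  expect_equal(unname(cb$per_variable), c(0.01, 0.09))
  expect_equal(cb$cf, mean(cb$per_variable))

  ## zero at identity; scale invariance under common positive rescaling
  expect_equal(cost_function(e2, e2)$cf, 0)
  expect_equal(cost_function(3.7 * e2, 3.7 * s2)$cf, cb$cf)
  ## square-root variant of the same metric
  expect_equal(cost_function(e1, s1, sqrt_metric = TRUE)$cf, 0.1)
  expect_error(cost_function(matrix(0, 1, 1), matrix(1, 1, 1)), "zero")
})

test_that("bounds are relative to nominal and sign-preserving", {
  ps <- parameter_set(c("lk", "ul", "neg"), nominal = c(10, 10, -2),
                      role = "gain_threshold",
                      measure_linked = c(TRUE, FALSE, TRUE))
  b <- make_bounds(ps)
  expect_equal(b$lower, c(7, 5, -2.6))
  expect_equal(b$upper, c(13, 15, -1.4))
  ## bounds reference nominal even after a warm start moved the value
  ps2 <- set_param_values(b, c(lk = 12.5))
  b2 <- make_bounds(ps2)
  expect_equal(b2$lower[1], 7)
  expect_equal(b2$upper[1], 13)
  ## overrides apply last; invalid overrides error
  b3 <- make_bounds(ps, overrides = list(lk = c(9, 11)))
  expect_equal(c(b3$lower[1], b3$upper[1]), c(9, 11))
  expect_error(make_bounds(ps, overrides = list(lk = c(2, 1))), "override")
})

test_that("CMA-ES reaches the sphere optimum, is seeded and never regresses", {
  ps <- parameter_set(c("a", "b", "c"), nominal = 0.5,
                      role = "gain_threshold", lower = 0, upper = 1,
                      value = c(0.1, 0.9, 0.2))
  sphere <- function(p) sum((param_values(p) - 0.5)^2)
  res <- cmaes_minimize(sphere, ps, c("a", "b", "c"),
                        optimizer_settings(seed = 7,
                                           max_evaluations = 2000))
  expect_lt(res$cf, 1e-8)

  ## same seed twice: identical trajectory and values
  res2 <- cmaes_minimize(sphere, ps, c("a", "b", "c"),
                         optimizer_settings(seed = 7,
                                            max_evaluations = 2000))
  expect_identical(res$params$value, res2$params$value)
  expect_identical(res$cf, res2$cf)

  ## empty free set is a no-op
  res0 <- cmaes_minimize(sphere, ps, character(0),
                         optimizer_settings(seed = 7))
  expect_identical(res0$params, ps)
  expect_equal(res0$cf, sphere(ps))
  expect_equal(res0$evaluations, 0L)

  ## best-of-run includes the start: a tiny budget cannot be worse
  tiny <- cmaes_minimize(sphere, ps, c("a", "b", "c"),
                         optimizer_settings(seed = 1,
                                            max_evaluations = 8))
  expect_lte(tiny$cf, sphere(ps))
  ## values stay within bounds
  expect_true(all(res$params$value >= res$params$lower &
                    res$params$value <= res$params$upper))

  expect_error(cmaes_minimize(function(p) NaN, ps, "a",
                              optimizer_settings(seed = 1)), "non-finite")
})

test_that("a noiseless record is recovered from a perturbed start", {
  model <- cr_surrogate()
  rec <- make_nominal_record()            # truth = nominal parameters
  std <- standardize_record(rec, model$parameters)
  sel <- select_parameters(model, std, rec, target_size = 4)
  ## perturb the base set away from truth, stay within bounds
  start <- std
  i <- match(sel$base_set, start$name)
  start$value[i] <- start$nominal[i] * 1.15
  fit <- fit_record(model, rec, start, sel,
                    settings = optimizer_settings(seed = 3))
  expect_lt(fit$cf_final$cf, fit$cf_initial$cf)
  expect_lt(fit$cf_final$cf, 1e-5)
  rec_err <- abs(param_values(fit$params, sel$base_set) -
                   param_values(std, sel$base_set)) /
    abs(param_values(std, sel$base_set))
  expect_true(all(rec_err < 0.05))
  ## monotone stage ledger: accepted stages never worsen the overall cost
  log <- fit$stage_log
  acc <- log[log$accepted, ]
  expect_true(all(diff(c(fit$cf_initial$cf, acc$cf_after)) <= 1e-12 |
                    acc$cf_after <= fit$cf_initial$cf))
  ## all values within bounds
  expect_true(all(fit$params$value >= fit$params$lower &
                    fit$params$value <= fit$params$upper))
})

test_that("an already-optimal start stays optimal through the stages", {
  model <- cr_surrogate()
  rec <- make_nominal_record()
  std <- standardize_record(rec, model$parameters)
  sel <- select_parameters(model, std, rec, target_size = 3)
  fit <- fit_record(model, rec, std, sel,
                    settings = optimizer_settings(seed = 5,
                                                  max_evaluations = 300))
  expect_lte(fit$cf_final$cf, fit$cf_initial$cf + 1e-15)
  expect_lt(fit$cf_initial$cf, 1e-12)  # noiseless record at truth
})

test_that("longitudinal fitting warm-starts and orders records", {
  model <- cr_surrogate()
  r1 <- make_nominal_record(record_id = "a", time_years = 0)
  r2 <- make_nominal_record(record_id = "b", time_years = 1)
  expect_error(fit_longitudinal(model, list(r2, r1)), "ordered")

  series <- fit_longitudinal(model, list(r1, r2),
                             optimizer_settings(seed = 2,
                                                max_evaluations = 400),
                             target_size = 3)
  expect_length(series$fits, 2L)
  ## identical records: the warm-started second fit is no worse
  expect_lte(series$fits[[2]]$cf_final$cf,
             series$fits[[1]]$cf_final$cf + 1e-12)
  expect_equal(series$factors$time, c(0, 1))

  ## single record equals fit_record from the standardized nominal start
  single <- fit_longitudinal(model, list(r1),
                             optimizer_settings(seed = 2,
                                                max_evaluations = 400),
                             target_size = 3)
  std <- standardize_record(r1, model$parameters)
  direct <- fit_record(model, r1, std, single$selection,
                       optimizer_settings(seed = 2, max_evaluations = 400))
  expect_equal(param_values(single$fits[[1]]$params),
               param_values(direct$params))
})

test_that("a drifting truth is tracked monotonically across records", {
  sc <- benchmark_scenario(seed = 42, noise_cv = 0)
  series <- fit_longitudinal(sc$model, sc$records,
                             optimizer_settings(seed = 42))
  gm <- vapply(series$fits, function(f) param_values(f$params, "Gm"), 0)
  expect_true(all(diff(gm) > 0))       # drift is upward at 5%/yr
  truth <- attr(sc$records, "truth")$S01
  rep <- parameter_recovery_report(truth, series$fits, names = "Gm")
  expect_true(all(rep$rel_error < 0.02))
})
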