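test_that("the prediction-error metric matches hand evaluations", {
  e <- matrix(10, 2, 2, dimnames = list(NULL, c("a", "b")))
  s <- e
  expect_equal(prediction_error(e, s)$overall_pe, 0)

  ## constant relative errors 0.1 and 0.3 average to 20%
  s2 <- e
  s2[, "a"] <- 9
  s2[, "b"] <- 7
  pe <- prediction_error(e, s2)
  expect_equal(pe$overall_pe, 20)
  expect_equal(pe$per_variable$median_pct, c(10, 30))
  expect_equal(pe$overall_pe, mean(pe$per_variable$median_pct),
               tolerance = 1e-9)

  ## one variable, constant 10% error
  e1 <- matrix(10, 3, 1, dimnames = list(NULL, "v"))
  expect_equal(prediction_error(e1, 0.9 * e1)$overall_pe, 10)

  ## scale invariance under common positive rescaling of a variable
  e3 <- e
  s3 <- s2
  e3[, "a"] <- e3[, "a"] * 50
  s3[, "a"] <- s3[, "a"] * 50
  expect_equal(prediction_error(e3, s3)$overall_pe, 20)

  ## zero experimental value names the cell
  ez <- e
  ez[2, "b"] <- 0
  expect_error(prediction_error(ez, s2), "variable b, level 2")

  ## multiple subjects pool into the per-variable median
  pe2 <- prediction_error(list(e, e), list(s2, e))
  expect_equal(pe2$n_subjects, 2L)
  expect_equal(pe2$per_variable$median_pct, c(5, 15))
})

test_that("Wilcoxon signed-rank equals exhaustive enumeration for n <= 12", {
  ## all-positive differences at n = 6: p = 2/64
  res <- wilcoxon_signed_rank(1:6, rep(0, 6))
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$statistic, 21)
  expect_equal(res$method, "exact")

  ## identical samples are degenerate with p = 1
  deg <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  ## random fixtures (with ties and zeros) against the 2^n oracle
  set.seed(99)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    d <- round(stats::rnorm(n), sample(0:2, 1))
    expect_equal(wilcoxon_signed_rank(d, numeric(n))$p_value,
                 brute_wilcoxon_p(d), tolerance = 1e-12,
                 info = paste("fixture", i))
  }

  ## tie-free case agrees with the reference implementation in stats
  set.seed(7)
  x <- stats::rnorm(10)
  y <- stats::rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               stats::wilcox.test(x, y, paired = TRUE,
                                  exact = TRUE)$p.value,
               tolerance = 1e-12)

  ## large n switches to the normal approximation and stays in [0, 1]
  set.seed(12)
  big <- wilcoxon_signed_rank(stats::rnorm(40, 0.3), stats::rnorm(40))
  expect_equal(big$method, "normal")
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("approach comparison pairs per-variable errors and flags ties", {
  model <- cr_surrogate()
  rec <- make_nominal_record()
  nominal <- standardize_record(rec, model$parameters)
  ## perturb gains touching every output so all 10 paired differences are
  ## non-zero
  perturbed <- set_param_values(
    nominal, param_values(nominal, c("Gm", "GHR", "GPM")) * 1.2,
    names = c("Gm", "GHR", "GPM"))

  ## equal parameter sets: identical reports, degenerate test
  cmp <- compare_approaches(model, rec,
                            list(time_specific = nominal,
                                 dynamic = nominal))
  expect_equal(cmp$pe$time_specific$overall_pe, cmp$pe$dynamic$overall_pe)
  expect_true(cmp$pairwise$degenerate[1])

  ## a perturbed set must be strictly worse on a noiseless record
  cmp2 <- compare_approaches(model, rec,
                             list(time_specific = nominal,
                                  single_time = perturbed))
  expect_lt(cmp2$pe$time_specific$overall_pe,
            cmp2$pe$single_time$overall_pe)
  ## single subject: 10 per-variable pairs feed the test
  expect_equal(cmp2$pairwise$n_pairs[1], 10L)

  ## preceding-threshold grid keeps the comparison honest for forecasts
  cmp3 <- compare_approaches(model, rec,
                             list(dynamic = nominal,
                                  single_time = perturbed),
                             at_grid = "preceding", preceding_at = 1.2)
  expect_equal(cmp3$at_grid, "preceding")
  expect_lt(cmp3$pe$dynamic$overall_pe, cmp3$pe$single_time$overall_pe)
})

test_that("validation report export writes JSON and CSV", {
  model <- cr_surrogate()
  rec <- make_nominal_record()
  nominal <- standardize_record(rec, model$parameters)
  cmp <- compare_approaches(model, rec,
                            list(time_specific = nominal,
                                 single_time = set_param_values(
                                   nominal,
                                   param_values(nominal, "GHR") * 1.1,
                                   names = "GHR")))
  json <- tempfile(fileext = ".json")
  csv <- tempfile(fileext = ".csv")
  export_validation_report(cmp, json, csv)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$approaches$time_specific$overall_pe,
               cmp$pe$time_specific$overall_pe)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 20L)         # 2 approaches x 10 variables
})
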