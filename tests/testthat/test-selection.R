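test_that("role classification partitions the parameter set", {
  model <- cr_surrogate()
  groups <- classify_by_role(model$parameters)
  expect_setequal(groups$gain_threshold,
                  c("Gc", "Gp", "Gm", "kVT", "GHR", "GPM", "GPP", "Bc",
                    "KpO2", "rI", "VTmax"))
  all_names <- unlist(groups)
  expect_setequal(all_names, model$parameters$name)
  expect_equal(length(all_names), nrow(model$parameters))  # partition

  one <- parameter_set("v", 1, role = "covariate")
  g1 <- classify_by_role(one)
  expect_equal(g1$covariate, "v")
  expect_equal(sum(lengths(g1)), 1L)

  empty <- parameter_set(character(0), numeric(0), character(0))
  expect_true(all(lengths(classify_by_role(empty)) == 0L))
  expect_length(classify_by_role(empty), 5L)
})

test_that("sensitivities of a linear toy model are analytic", {
  toy <- make_toy_linear_model()
  stimuli <- data.frame(vo2 = c(0.5, 1, 1.5), vco2 = c(0.5, 1, 1.5))
  sm <- build_sensitivity_matrix(toy, toy$parameters, stimuli)
  ## y = a*x: relative sensitivity to a is exactly 1 on y rows
  expect_equal(unname(sm$S[sm$row_variable == "y", "a"]), rep(1, 3),
               tolerance = 1e-9)
  ## inert parameter: zero column
  expect_equal(unname(sm$S[, "c"]), rep(0, 6))
  ## exp data equal to model output: all weights zero
  y0 <- toy$simulate(param_values(toy$parameters), stimuli$vo2, stimuli$vco2)
  sm2 <- build_sensitivity_matrix(toy, toy$parameters, stimuli,
                                  exp_data = y0)
  expect_true(all(sm2$row_weights == 0))
})

test_that("base-set selection is greedy, identifiable and order-invariant", {
  ## two orthogonal unit columns: both selected, index 1
  sm <- structure(list(S = cbind(p1 = c(1, 0), p2 = c(0, 1)),
                       row_weights = c(1, 1),
                       row_variable = c("u", "v"), row_level = c(1L, 1L),
                       variables = c("u", "v")),
                  class = "sensitivity_matrix")
  sel <- select_base_set(sm, target_size = 2)
  expect_setequal(as.character(sel), c("p1", "p2"))
  d <- attr(sel, "diagnostics")
  expect_true(all(d$collinearity_at_inclusion[d$selected] <= 15))

  ## duplicated column: only one of the pair enters
  smd <- sm
  smd$S <- cbind(p1 = c(1, 1), p2 = c(1, 1), p3 = c(1, -1)) / sqrt(2)
  sel2 <- select_base_set(smd, target_size = 2)
  expect_length(sel2, 2L)
  expect_true(sum(c("p1", "p2") %in% sel2) == 1L)

  ## target 1 picks the highest total sensitivity
  smr <- sm
  smr$S <- cbind(weak = c(0.1, 0), strong = c(0, 2))
  expect_equal(as.character(select_base_set(smr, target_size = 1)), "strong")

  ## permutation invariance (ties broken by name)
  smp <- smd
  smp$S <- smd$S[, c(3, 1, 2)]
  expect_setequal(as.character(select_base_set(smp, target_size = 2)),
                  as.character(sel2))

  expect_error(select_base_set(structure(list(
    S = cbind(a = c(0, 0)), row_weights = c(1, 1),
    row_variable = c("u", "v"), row_level = c(1L, 1L),
    variables = c("u", "v")), class = "sensitivity_matrix")), "zero")
})

test_that("specific sets demand dominant single-variable sensitivity", {
  sm <- structure(list(
    S = cbind(only_u = c(0.5, 0), both = c(1, 1)),
    row_weights = c(1, 1), row_variable = c("u", "v"),
    row_level = c(1L, 1L), variables = c("u", "v")),
    class = "sensitivity_matrix")
  sp <- select_specific_sets(sm, base_set = character(0),
                             dominance_ratio = 2)
  expect_equal(sp$u, "only_u")         # infinite dominance
  expect_length(sp$v, 0L)              # "both" has ratio 1 everywhere

  ## all parameters equally affecting all variables select nothing
  sme <- sm
  sme$S <- cbind(a = c(1, 1), b = c(2, 2))
  spe <- select_specific_sets(sme, base_set = character(0),
                              dominance_ratio = 2)
  expect_true(all(lengths(spe) == 0L))
})

test_that("the heart-rate gain is the surrogate's specific parameter for hr", {
  model <- cr_surrogate()
  rec <- make_nominal_record()
  sel <- select_parameters(model, model$parameters, rec,
                           target_size = 6)
  ## GHR affects only hr; if not in the base set it must win hr's specific set
  if (!"GHR" %in% sel$base_set) {
    expect_equal(sel$specific_sets$hr, "GHR")
  } else {
    smx <- sel$sensitivity
    hr_rows <- smx$row_variable == "hr"
    expect_true(all(abs(smx$S[!hr_rows, "GHR"]) < 1e-9))
  }
  ## base and specific sets are disjoint
  expect_length(intersect(sel$base_set, unlist(sel$specific_sets)), 0L)
})

test_that("selection diagnostics export round-trips", {
  model <- cr_surrogate()
  rec <- make_nominal_record()
  sel <- select_parameters(model, model$parameters, rec)
  csv <- tempfile(fileext = ".csv")
  export_selection_diagnostics(sel, csv)
  d <- utils::read.csv(csv)
  expect_true(all(c("name", "total_sensitivity", "selected_for") %in%
                    names(d)))
  expect_true(all(sel$base_set %in% d$name[d$selected_for == "base"]))
})
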