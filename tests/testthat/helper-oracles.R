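# Independent oracles and shared fixtures for the test suite.

# Bisection root of the ventilation residual, independent of the package's
# own bracketed-secant solver.
bisect_ve <- function(model, params, vo2, vco2, lo = 0.5, hi = 2000,
                      iters = 60L) {
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    r <- ventilation_residual(mid, model, params, vo2 = vo2, vco2 = vco2)
    if (r < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force two-sided Wilcoxon signed-rank p-value by enumeration of all
# 2^n sign assignments (midranks under ties).
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# A self-consistent noiseless record on the surrogate's nominal parameters.
make_nominal_record <- function(at = 1.4, n_levels = 8L, record_id = "r1",
                                time_years = 0) {
  model <- cr_surrogate()
  grid <- stimulus_grid(at, n_levels)
  obs <- simulate_steady_state(model, vo2 = grid$vo2, vco2 = grid$vco2)
  longitudinal_record(
    record_id = record_id, subject_id = "s1", time_years = time_years,
    anthro = list(height = 167.4, weight = 83.3, age = 30),
    env = list(fio2 = 21.0379, fico2 = 0.0421, patm = 640),
    factors = list(activity = 5, sleep = 7),
    at_vco2 = at, vtn = 0.6, stimulus = grid, observations = obs)
}

# Toy linear model y = a * x at fixed stimulus, for analytic sensitivity
# checks: relative sensitivity of y to a is exactly 1, and to the inert
# parameter c is exactly 0.
make_toy_linear_model <- function() {
  params <- parameter_set(c("a", "c"), nominal = c(2, 5),
                          role = "gain_threshold")
  list(name = "toy", parameters = params, variables = c("y", "z"),
       simulate = function(values, vo2, vco2) {
         cbind(y = values[["a"]] * vo2, z = rep(1, length(vo2)) + 0 * vco2)
       })
}
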