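## Covariance Matrix Adaptation Evolution Strategy on the unit box.
##
## Standard (mu/mu_w, lambda) CMA-ES with rank-one and rank-mu covariance
## updates and cumulative step-size adaptation. Candidates outside [0,1]^d
## are evaluated at their clipped image with a quadratic out-of-box penalty
## added, which keeps the returned optimum feasible while preserving a
## smooth selection gradient back into the box. The start point itself is
## evaluated first, so the best-of-run can never be worse than the start.

cma_es_unit <- function(fn, x0, sigma0 = 0.3, popsize = NULL,
                        max_evaluations = NULL, tol_fun = 1e-9,
                        penalty_weight = 1e4) {
  d <- length(x0)
  if (is.null(popsize)) popsize <- 4L + floor(3 * log(d))
  popsize <- max(4L, as.integer(popsize))
  if (is.null(max_evaluations)) max_evaluations <- 500L * d
  mu <- floor(popsize / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  cs <- (mueff + 2) / (d + mueff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  eval_clipped <- function(x) {
    xc <- pmin(pmax(x, 0), 1)
    f <- fn(xc)
    list(f = f + penalty_weight * sum((x - xc)^2), f_raw = f, x = xc)
  }

  xmean <- pmin(pmax(x0, 0), 1)
  start <- eval_clipped(xmean)
  evals <- 1L
  best <- list(x = start$x, f = start$f_raw)
  pc <- ps <- numeric(d)
  B <- diag(d)
  D <- rep(1, d)
  C <- diag(d)
  sigma <- sigma0

  while (evals < max_evaluations && best$f > tol_fun) {
    lam <- min(popsize, max_evaluations - evals)
    if (lam < 4L) break
    Z <- matrix(stats::rnorm(d * lam), d, lam)
    Y <- B %*% (D * Z)                    # N(0, C) steps
    X <- xmean + sigma * Y
    fs <- numeric(lam)
    for (j in seq_len(lam)) {
      ev <- eval_clipped(X[, j])
      fs[j] <- ev$f
      if (ev$f_raw < best$f && all(X[, j] >= -1e-12) && all(X[, j] <= 1 + 1e-12)) {
        best <- list(x = ev$x, f = ev$f_raw)
      } else if (ev$f < best$f) {
        ## out-of-box candidate whose clipped image still improves
        best <- list(x = ev$x, f = ev$f_raw)
      }
    }
    evals <- evals + lam
    sel <- order(fs)[seq_len(mu)]
    ymean <- as.vector(Y[, sel, drop = FALSE] %*% w)
    xmean <- xmean + sigma * ymean
    ## cumulation
    invsqrtC_y <- as.vector(B %*% ((t(B) %*% ymean) / D))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * invsqrtC_y
    hsig <- as.numeric(sum(ps^2) / (1 - (1 - cs)^(2 * evals / lam)) / d <
                         2 + 4 / (d + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean
    ## covariance update
    artmp <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sigma) || sigma > 1e3) sigma <- 1e3
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    if (sigma * max(D) < 1e-12) break
  }
  list(x = best$x, f = best$f, evaluations = evals)
}

#' Bounded CMA-ES minimization over selected parameters
#'
#' Minimizes an objective over a subset of parameters with the Covariance
#' Matrix Adaptation Evolution Strategy. The free parameters are mapped
#' affinely onto the unit box from their absolute bounds; candidates
#' leaving the box are clipped before evaluation with a quadratic
#' out-of-box penalty. The best point of the run, including the start
#' point, is returned, so the result is never worse than the start. The
#' run is reproducible given the seed in `settings`.
#'
#' @param objective function taking a [parameter_set()] and returning a
#'   finite scalar cost (non-finite start is an error; non-finite candidate
#'   values are treated as very poor).
#' @param start a `parameter_set` giving the start point (within bounds).
#' @param free names of the parameters to optimize; the rest stay fixed.
#'   An empty `free` returns the start unchanged.
#' @param settings an [optimizer_settings()].
#' @return List with `params` (best parameter set), `cf` (best cost),
#'   `evaluations`, and `seed`.
#' @export
cmaes_minimize <- function(objective, start, free,
                           settings = optimizer_settings()) {
  if (!length(free)) {
    return(list(params = start, cf = objective(start), evaluations = 0L,
                seed = settings$seed))
  }
  i <- param_index(start, free)
  lo <- start$lower[i]
  hi <- start$upper[i]
  to_unit <- function(v) (v - lo) / (hi - lo)
  from_unit <- function(u) lo + u * (hi - lo)
  fn <- function(u) {
    ps <- set_param_values(start, from_unit(u), names = free, clip = TRUE)
    f <- objective(ps)
    if (!is.finite(f)) f <- 1e12
    f
  }
  f0 <- objective(start)
  if (!is.finite(f0)) stop("objective is non-finite at the start point")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(settings$seed)
  res <- cma_es_unit(fn, to_unit(start$value[i]), sigma0 = settings$sigma0,
                     popsize = settings$popsize,
                     max_evaluations = settings$max_evaluations,
                     tol_fun = settings$tol_cf)
  params <- set_param_values(start, from_unit(res$x), names = free,
                             clip = TRUE)
  cf <- res$f
  if (f0 <= cf) {                        # best-of-run includes the start
    params <- start
    cf <- f0
  }
  list(params = params, cf = cf, evaluations = res$evaluations,
       seed = settings$seed)
}
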