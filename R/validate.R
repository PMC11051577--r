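#' Median relative prediction error of a fitting approach
#'
#' The prediction error (PE) metric summarizes how well a parameter set
#' reproduces the steady-state measurements: for each variable, the median
#' over all subjects and stimulus levels of the absolute relative error
#' `|yexp - ysim| / yexp` is taken, and the overall PE is 100 times the
#' mean of those per-variable medians — a median-based variant of the mean
#' absolute error expressed as a percentage of the experimental data.
#'
#' @param exp_data,sim_data either matrices `K x I` (levels by variables,
#'   one subject) or lists of such matrices (one per subject), with
#'   matching shapes and variable columns.
#' @return An object of class `pe_report`: list with `overall_pe` (%),
#'   `per_variable` (data frame: variable, median %, IQR %), `n_subjects`,
#'   `n_variables`, `n_levels`.
#' @examples
#' e <- matrix(10, 2, 2, dimnames = list(NULL, c("a", "b")))
#' s <- matrix(c(9, 9, 7, 7), 2, 2, dimnames = list(NULL, c("a", "b")))
#' prediction_error(e, s)$overall_pe # (10% + 30%) / 2 = 20
#' @export
prediction_error <- function(exp_data, sim_data) {
  if (!is.list(exp_data)) exp_data <- list(exp_data)
  if (!is.list(sim_data)) sim_data <- list(sim_data)
  stopifnot(length(exp_data) == length(sim_data))
  vars <- colnames(exp_data[[1L]])
  rel <- lapply(seq_along(exp_data), function(j) {
    e <- as.matrix(exp_data[[j]])
    s <- as.matrix(sim_data[[j]])
    if (!identical(dim(e), dim(s))) stop("shape mismatch for subject ", j)
    if (!is.null(colnames(s))) s <- s[, vars, drop = FALSE]
    if (any(e == 0)) {
      bad <- which(e == 0, arr.ind = TRUE)[1L, ]
      stop("zero experimental value for subject ", j, ", variable ",
           vars[bad[2L]], ", level ", bad[1L])
    }
    abs(e - s) / abs(e)
  })
  per_var <- vapply(seq_along(vars), function(i) {
    x <- unlist(lapply(rel, function(m) m[, i]))
    c(median = stats::median(x), iqr = stats::IQR(x))
  }, numeric(2))
  per_variable <- data.frame(variable = vars,
                             median_pct = 100 * per_var["median", ],
                             iqr_pct = 100 * per_var["iqr", ],
                             row.names = NULL)
  structure(list(overall_pe = mean(per_variable$median_pct),
                 per_variable = per_variable,
                 n_subjects = length(exp_data),
                 n_variables = length(vars),
                 n_levels = nrow(exp_data[[1L]])),
            class = "pe_report")
}

#' @export
print.pe_report <- function(x, ...) {
  cat("<pe_report> overall PE ", round(x$overall_pe, 2), "% (",
      x$n_subjects, " subject(s), ", x$n_variables, " variables, ",
      x$n_levels, " levels)\n", sep = "")
  invisible(x)
}

## Exact null distribution of the positive-rank sum W+ by convolution over
## sign assignments: each rank r contributes a factor (1 + z^r). Ranks may
## be midranks (half-integers under ties), so everything is doubled to stay
## on an integer lattice.
wilcoxon_exact_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1L)          # index s+1 holds count of sum s
  dist[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1L - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w2 <- round(2 * w)
  p_le <- sum(dist[(seq_along(dist) - 1) <= w2 + 1e-9])
  p_ge <- sum(dist[(seq_along(dist) - 1) >= w2 - 1e-9])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided Wilcoxon signed-rank test of whether the paired differences
#' `x - y` are symmetrically distributed around zero. Zero differences are
#' dropped; ties are mid-ranked. For `n <= exact_limit` non-zero pairs the
#' p-value comes from the exact null distribution of the positive-rank sum
#' (enumerated by convolution over all `2^n` sign assignments); above that,
#' from the normal approximation with continuity and tie corrections.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit maximum `n` for the exact null (default 25).
#' @return List with `p_value`, `statistic` (positive-rank sum `W+`), `n`
#'   (non-zero pairs), `method` (`"exact"`, `"normal"`, or
#'   `"degenerate"`), and `degenerate` (`TRUE` when all differences were
#'   zero, in which case `p_value = 1` by convention).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(p_value = 1, statistic = 0, n = 0L, method = "degenerate",
                degenerate = TRUE))
  }
  ranks <- rank(abs(d))                # midranks under ties
  w <- sum(ranks[d > 0])
  if (n <= exact_limit) {
    p <- wilcoxon_exact_p(w, ranks)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(p_value = p, statistic = w, n = n, method = method,
       degenerate = FALSE)
}

#' Compare the three fitting approaches on held-out records
#'
#' Simulates each record's stimulus grid under the parameter sets of the
#' three approaches — time-specific (fitted to the record itself),
#' single-time (the first record's fit carried forward), and dynamic
#' (parameters predicted by the ARX trend models) — computes a
#' [prediction_error()] report per approach, and tests each pair of
#' approaches with the Wilcoxon signed-rank test on paired
#' per-(subject, variable) median absolute relative errors.
#'
#' When `at_grid = "preceding"`, the simulation grid for each record is
#' rebuilt from the preceding record's anaerobic threshold (the situation
#' of a genuine forecast, where the future threshold is unknown) and the
#' experimental observations are interpolated onto it; with `"own"` the
#' record's measured grid is used directly.
#'
#' @param model a model object (see [cr_surrogate()]).
#' @param records list of held-out [longitudinal_record()]s (one per
#'   subject, or several).
#' @param param_sets named list of approaches; each element is either one
#'   [parameter_set()] applied to all records or a list of sets aligned
#'   with `records`. Standard names: `time_specific`, `single_time`,
#'   `dynamic`.
#' @param at_grid `"own"` or `"preceding"`; with `"preceding"`,
#'   `preceding_at` must give the preceding record's threshold per record.
#' @param preceding_at numeric vector of preceding-record anaerobic
#'   thresholds (L/min), recycled over records.
#' @param rer respiratory exchange ratio for grid construction.
#' @return An object of class `comparison_report`: list with `pe` (one
#'   `pe_report` per approach), `pairwise` (data frame: pair, p-value,
#'   significance flags at 0.05 and 0.01), and `pairing` (description of
#'   the pairing unit).
#' @export
compare_approaches <- function(model, records, param_sets,
                               at_grid = c("own", "preceding"),
                               preceding_at = NULL, rer = 0.9) {
  at_grid <- match.arg(at_grid)
  if (!is.list(records) || inherits(records, "longitudinal_record")) {
    records <- list(records)
  }
  approaches <- names(param_sets)
  if (at_grid == "preceding" && is.null(preceding_at)) {
    stop("at_grid = \"preceding\" requires preceding_at")
  }
  if (!is.null(preceding_at)) {
    preceding_at <- rep_len(preceding_at, length(records))
  }
  sims <- list()
  exps <- list()
  for (j in seq_along(records)) {
    rec <- records[[j]]
    if (at_grid == "preceding") {
      grid <- stimulus_grid(preceding_at[j], nrow(rec$stimulus), rer = rer)
      exp_j <- apply(rec$observations, 2, function(y) {
        stats::approx(rec$stimulus$vco2, y, xout = grid$vco2, rule = 2)$y
      })
    } else {
      grid <- rec$stimulus
      exp_j <- rec$observations
    }
    exps[[j]] <- exp_j
    for (a in approaches) {
      ps <- param_sets[[a]]
      if (is.list(ps) && !inherits(ps, "parameter_set")) ps <- ps[[j]]
      sims[[a]][[j]] <- tryCatch(
        model$simulate(param_values(ps), grid$vo2, grid$vco2),
        error = function(e) NULL)
    }
  }
  pe <- list()
  med_by_subj_var <- list()
  for (a in approaches) {
    if (any(vapply(sims[[a]], is.null, NA))) {
      pe[[a]] <- NULL                  # approach unavailable
      next
    }
    pe[[a]] <- prediction_error(exps, sims[[a]])
    med_by_subj_var[[a]] <- unlist(lapply(seq_along(records), function(j) {
      rel <- abs(exps[[j]] - sims[[a]][[j]]) / abs(exps[[j]])
      apply(rel, 2, stats::median)
    }))
  }
  avail <- names(Filter(Negate(is.null), pe))
  pairs <- if (length(avail) >= 2L) utils::combn(avail, 2L) else
    matrix(character(0), 2L, 0L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    wt <- wilcoxon_signed_rank(med_by_subj_var[[a]], med_by_subj_var[[b]])
    data.frame(approach_a = a, approach_b = b, p_value = wt$p_value,
               n_pairs = wt$n, degenerate = wt$degenerate,
               sig_0.05 = !wt$degenerate & wt$p_value < 0.05,
               sig_0.01 = !wt$degenerate & wt$p_value < 0.01)
  }))
  if (is.null(pairwise)) {
    pairwise <- data.frame(approach_a = character(), approach_b = character(),
                           p_value = numeric(), n_pairs = integer(),
                           degenerate = logical(), sig_0.05 = logical(),
                           sig_0.01 = logical())
  }
  structure(list(pe = pe, pairwise = pairwise,
                 pairing = "per (subject, variable) median absolute relative error",
                 at_grid = at_grid),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  for (a in names(x$pe)) {
    if (is.null(x$pe[[a]])) next
    cat(sprintf("  %-14s overall PE %6.2f %%\n", a, x$pe[[a]]$overall_pe))
  }
  if (nrow(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise))) {
      r <- x$pairwise[i, ]
      stars <- if (r$degenerate) "(degenerate)" else
        if (r$sig_0.01) "**" else if (r$sig_0.05) "*" else "ns"
      cat(sprintf("  %s vs %s: p = %.4g %s\n", r$approach_a, r$approach_b,
                  r$p_value, stars))
    }
  }
  invisible(x)
}

#' Export a validation report
#'
#' Writes the per-approach PE summaries and pairwise Wilcoxon results as
#' JSON, with the per-variable medians/IQRs additionally as CSV.
#'
#' @param report a [compare_approaches()] result.
#' @param json_path output JSON path.
#' @param csv_path optional per-variable CSV path.
#' @return Invisibly, `json_path`.
#' @export
export_validation_report <- function(report, json_path, csv_path = NULL) {
  out <- list(
    pairing = report$pairing, at_grid = report$at_grid,
    approaches = lapply(report$pe, function(p) {
      if (is.null(p)) return(NULL)
      list(overall_pe = p$overall_pe, per_variable = p$per_variable,
           n_subjects = p$n_subjects, n_levels = p$n_levels)
    }),
    pairwise = report$pairwise)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!is.null(csv_path)) {
    tabs <- do.call(rbind, lapply(names(report$pe), function(a) {
      p <- report$pe[[a]]
      if (is.null(p)) return(NULL)
      cbind(approach = a, p$per_variable)
    }))
    utils::write.csv(tabs, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
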