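#' Perturb a dataset within its measurement uncertainties
#'
#' Resamples each activity from Normal(value, sigma), truncated at
#' zero, leaving times and sigmas untouched. One draw of the parametric
#' bootstrap behind the Monte Carlo uncertainty estimate.
#'
#' @param dataset A [biokin_dataset] with a finite `sigma` on every
#'   point.
#' @param seed Integer seed; the perturbation is reproducible given it.
#' @return The perturbed dataset.
#' @export
perturb_dataset <- function(dataset, seed = 1L) {
  p <- dataset$points
  if (any(!is.finite(p$sigma)))
    stop("every point needs a sigma before perturbation")
  set.seed(seed)
  p$value <- pmax(stats::rnorm(nrow(p), p$value, p$sigma), 0)
  dataset$points <- p
  dataset
}

#' Monte Carlo parameter uncertainty by refitting perturbed data
#'
#' Repeats perturb-then-refit: each run perturbs the measurements
#' within their uncertainties and refits the full model; parameter
#' uncertainty is reported as the standard deviation of the best-fit
#' values across runs. Run r derives its two seeds (data perturbation
#' and annealer) deterministically from the master seed, so the whole
#' table is reproducible. Individual run failures are logged and
#' excluded, not fatal.
#'
#' @inheritParams fit_full_model
#' @param runs Number of Monte Carlo runs; the study used 100 (reduce
#'   for quick checks).
#' @param fit_args Extra arguments passed on to [fit_full_model()]
#'   (e.g. `control`, `constraints`, `init`).
#' @return Object of class `uncertainty_result`: data frame `summary`
#'   (parameter, mean, sd), matrix `runs_table` (runs x parameters),
#'   counts of requested/failed runs, master seed.
#' @export
mc_uncertainty <- function(dataset, structure,
                           lambda = decay_constant("I131"),
                           runs = 100L, seed = 1L, fit_args = list()) {
  if (runs < 2) stop("need at least 2 runs")
  rows <- list()
  failures <- 0L
  for (r in seq_len(runs)) {
    pert <- perturb_dataset(dataset, seed = seed + r)
    fit <- try(do.call(fit_full_model,
                       c(list(dataset = pert, structure = structure,
                              lambda = lambda, seed = seed + 100003L + r),
                         fit_args)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      failures <- failures + 1L
      message("run ", r, " failed: ", attr(fit, "condition")$message)
      next
    }
    rows[[length(rows) + 1L]] <- c(fit$params$rates,
                                   fit$params$blood_fractions)
  }
  if (length(rows) < 2) stop("fewer than 2 successful runs")
  tab <- do.call(rbind, rows)
  out <- list(summary = data.frame(parameter = colnames(tab),
                                   mean = colMeans(tab),
                                   sd = apply(tab, 2, stats::sd),
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
              runs_table = tab, runs_requested = runs,
              runs_failed = failures, seed = seed)
  class(out) <- "uncertainty_result"
  out
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat("<uncertainty_result> ", nrow(x$runs_table), "/", x$runs_requested,
      " runs (", x$runs_failed, " failed)\n", sep = "")
  print(transform(x$summary, mean = signif(mean, 3), sd = signif(sd, 2)))
  invisible(x)
}
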