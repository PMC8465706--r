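#' Joint fit across subjects with tied parameters
#'
#' Fits one structure to several subjects' datasets simultaneously:
#' parameters named in `free` take an independent value per subject
#' (here typically the tumor rates, which differ between tumor cell
#' lines), all others are shared. The objective is the summed WRSS.
#'
#' @param datasets List of [biokin_dataset]s, one per subject.
#' @param structure A [model_structure] common to all subjects.
#' @param free Character vector of parameter names (rates and/or
#'   blood-fraction parameters) allowed to vary per subject; may be
#'   empty. Must name existing parameters.
#' @inheritParams fit_full_model
#' @return A `biokin_fit` whose `$params` carries the shared values and
#'   `$subject_params` a per-subject list of complete [parameter_set]s.
#' @export
fit_joint <- function(datasets, structure, free = character(),
                      lambda = decay_constant("I131"), init = NULL,
                      constraints = fit_constraints(),
                      ref_blood_fractions = NULL,
                      seed = 1L, control = list(), polish = TRUE) {
  if (!length(datasets)) stop("no datasets supplied")
  evs <- lapply(datasets, make_wrss_evaluator, structure = structure,
                lambda = lambda)
  rate_names <- structure$edges$rate
  bf_all <- unique(unlist(lapply(evs, `[[`, "bf_names")))
  par_names <- c(rate_names, bf_all)
  if (anyDuplicated(free)) stop("parameter tying groups overlap")
  unknown <- setdiff(free, par_names)
  if (length(unknown))
    stop("free parameters not in the model: ", paste(unknown, collapse = ", "))
  shared <- setdiff(par_names, free)
  ns <- length(datasets)
  ref <- ref_blood_fractions %||% clr_reference_blood_fractions()
  one_bounds <- function(names) {
    is_rate <- names %in% rate_names
    bfn <- names[!is_rate]
    bb <- if (length(bfn)) bf_bounds(bfn, ref, constraints$bf_window)
    list(lower = c(rep(constraints$rate_lower, sum(is_rate)), bb$lower),
         upper = c(rep(constraints$rate_upper, sum(is_rate)), bb$upper),
         log_space = c(rep(TRUE, sum(is_rate)), rep(FALSE, length(bfn))),
         start = c(rep(sqrt(constraints$rate_lower * constraints$rate_upper),
                       sum(is_rate)), bb$ref),
         names = c(names[is_rate], bfn))
  }
  bs <- one_bounds(shared)
  bfr <- one_bounds(free)
  lower <- c(bs$lower, rep(bfr$lower, ns))
  upper <- c(bs$upper, rep(bfr$upper, ns))
  log_space <- c(bs$log_space, rep(bfr$log_space, ns))
  start <- c(bs$start, rep(bfr$start, ns))
  if (!is.null(init)) {
    vals <- c(init$rates, init$blood_fractions)
    start <- pmin(pmax(c(vals[bs$names], rep(vals[bfr$names], ns)),
                       lower), upper)
  }
  nsh <- length(shared); nfr <- length(free)
  assemble <- function(theta, j) {
    full <- stats::setNames(numeric(length(par_names)), par_names)
    full[bs$names] <- theta[seq_len(nsh)]
    if (nfr)
      full[bfr$names] <- theta[nsh + (j - 1) * nfr + seq_len(nfr)]
    full
  }
  obj_resid <- function(theta) {
    unlist(lapply(seq_len(ns), function(j) {
      full <- assemble(theta, j)
      evs[[j]]$resid(full[rate_names], full[bf_all])
    }))
  }
  obj <- function(theta) sum(obj_resid(theta)^2)
  sa <- simulated_annealing(obj, start, lower, upper, log_space,
                            control = control, seed = seed)
  best <- sa
  if (polish) {
    # refine from the annealing incumbent and from the start point: with
    # a good initial guess (e.g. decoupling values) the latter guards
    # against a short annealing run drifting basins
    for (p0 in list(sa$par, start)) {
      pol <- polish_lm(obj_resid, p0, lower, upper, log_space)
      if (pol$value < best$value) best <- pol
    }
  }
  subject_params <- lapply(seq_len(ns), function(j) {
    full <- assemble(best$par, j)
    parameter_set(full[rate_names], full[bf_all], lambda)
  })
  shared_full <- assemble(best$par, 1)
  params <- parameter_set(shared_full[rate_names], shared_full[bf_all], lambda)
  N <- sum(vapply(evs, `[[`, numeric(1), "n_points"))
  K <- nsh + ns * nfr
  new_fit_result(params, best$value, N = N, K = K, trace = sa$trace,
                 seed = seed, evaluations = sa$evaluations,
                 extra = list(subject_params = subject_params,
                              free = free, shared = shared))
}
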