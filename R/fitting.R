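#' Weighted residual sum of squares
#'
#' The fit objective: squared residuals weighted by the inverse
#' measurement variance, summed over all organs and time points,
#' \eqn{WRSS = \sum_s \sum_p (A^{obs}_{s,p} - A^{th}_{s,p})^2 /
#' \sigma_{s,p}^2}.
#'
#' @param observed,predicted Numeric vectors aligned point-by-point.
#' @param sigma Positive standard deviations, same length.
#' @return Non-negative scalar.
#' @export
wrss <- function(observed, predicted, sigma) {
  if (length(observed) != length(predicted) ||
      length(observed) != length(sigma))
    stop("observed, predicted and sigma must be aligned")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all sigma must be positive")
  sum(((observed - predicted) / sigma)^2)
}

# precompiled WRSS evaluator for a dataset against a structure: returns
# function(rates, bfs) -> WRSS, with all indexing resolved up front
make_wrss_evaluator <- function(dataset, structure, lambda, y0 = NULL) {
  p <- dataset$points
  organs <- intersect(names(structure$observations), unique(p$organ))
  skipped <- setdiff(names(structure$observations), c(organs, "blood"))
  p <- p[p$organ %in% organs, , drop = FALSE]
  if (!nrow(p)) stop("dataset has no points for any observed organ")
  if (any(!is.finite(p$sigma) | p$sigma <= 0))
    stop("all fitted points need positive sigma (see assign_uncertainties)")
  comp <- structure$compartments
  n <- length(comp)
  ef <- match(structure$edges$from, comp)
  et <- match(structure$edges$to, comp)
  rate_names <- structure$edges$rate
  blood_i <- match("blood", comp)
  W0 <- matrix(0, length(organs), n, dimnames = list(organs, comp))
  bf_of_organ <- stats::setNames(rep(NA_character_, length(organs)), organs)
  for (org in organs) {
    ob <- structure$observations[[org]]
    W0[org, ob$compartments] <- 1
    bf_of_organ[org] <- ob$blood_fraction
  }
  times <- sort(unique(p$time_h))
  ti <- match(p$time_h, times)
  oi <- match(p$organ, organs)
  if (is.null(y0)) {
    y0v <- numeric(n); y0v[blood_i] <- 100
  } else y0v <- unname(y0[comp])
  obs <- p$value; sig <- p$sigma
  # precomputed indexing so each evaluation is a handful of vector ops
  off_idx <- cbind(et, ef)
  G <- matrix(0, n, length(ef))        # outflow incidence: diag = -G %*% k
  if (length(ef)) G[cbind(ef, seq_along(ef))] <- 1
  diag_idx <- cbind(seq_len(n), seq_len(n))
  has_bf <- !is.na(bf_of_organ)
  resid_fn <- function(rates, bfs = numeric()) {
    M <- matrix(0, n, n)
    M[off_idx] <- rates
    M[diag_idx] <- -as.vector(G %*% rates) - lambda
    Y <- expm_action(M, y0v, times)
    W <- W0
    if (any(has_bf) && length(bfs))
      W[has_bf, blood_i] <- W[has_bf, blood_i] + bfs[bf_of_organ[has_bf]]
    pred <- (Y %*% t(W))[cbind(ti, oi)]
    (obs - pred) / sig
  }
  eval_fn <- function(rates, bfs = numeric()) sum(resid_fn(rates, bfs)^2)
  list(fn = eval_fn, resid = resid_fn, rate_names = rate_names,
       bf_names = unique(stats::na.omit(bf_of_organ)),
       n_points = nrow(p), organs = organs, skipped = skipped)
}

#' Bounds and windows used during optimization
#'
#' @param rate_lower,rate_upper Box bounds for all rate constants
#'   \[h^-1\]; defaults 1e-8 and 1e2 span the published values by more
#'   than two decades on either side.
#' @param bf_window Half-width of the blood-fraction window as a
#'   fraction of the reference value; the study used +/-30%.
#' @return List of class `fit_constraints`.
#' @export
fit_constraints <- function(rate_lower = 1e-8, rate_upper = 1e2,
                            bf_window = 0.30) {
  stopifnot(rate_lower > 0, rate_lower <= rate_upper, bf_window >= 0)
  out <- list(rate_lower = rate_lower, rate_upper = rate_upper,
              bf_window = bf_window)
  class(out) <- "fit_constraints"
  out
}

bf_bounds <- function(bf_names, reference, window) {
  ref <- reference[bf_names]
  if (any(is.na(ref)))
    stop("no reference blood fraction for: ",
         paste(bf_names[is.na(ref)], collapse = ", "))
  list(lower = pmax(ref * (1 - window), 0),
       upper = pmin(ref * (1 + window), 1),
       ref = ref)
}

new_fit_result <- function(params, wrss, N, K, trace = NULL, seed = NA,
                           evaluations = NA, extra = list()) {
  gof <- if (N > K) wrss / (N - K) else NA_real_
  aic <- if (N > K + 1 && wrss > 0) aicc(wrss, N, K) else NA_real_
  out <- c(list(params = params, wrss = wrss, N = N, K = K,
                gof = gof, aicc = aic, trace = trace, seed = seed,
                evaluations = evaluations), extra)
  class(out) <- "biokin_fit"
  out
}

#' @export
print.biokin_fit <- function(x, ...) {
  cat("<biokin_fit> WRSS = ", signif(x$wrss, 6), ", N = ", x$N,
      ", K = ", x$K, ", WRSS/(N-K) = ", signif(x$gof, 4),
      ", AICc = ", signif(x$aicc, 6), "\n", sep = "")
  invisible(x)
}

#' Fit the complete compartmental model to a dataset
#'
#' Joint simulated-annealing fit of all rate constants and blood
#' fractions against every observed series, with blood treated as a
#' state (bolus initial condition), followed by a local refinement from
#' the annealing incumbent. Rates are searched in log space within the
#' constraint box; blood fractions within a +/- window around their
#' reference values.
#'
#' @param dataset A [biokin_dataset] with positive `sigma` everywhere.
#'   Organs in the structure without data are dropped from the objective
#'   with a warning.
#' @param structure A [model_structure].
#' @param lambda Physical decay constant \[h^-1\].
#' @param init Optional [parameter_set] used as the starting point;
#'   defaults to mid-box rates and reference blood fractions.
#' @param constraints A [fit_constraints].
#' @param ref_blood_fractions Named vector of reference blood fractions
#'   (as fractions) keyed by blood-fraction parameter name; defaults to
#'   the shipped human reference table.
#' @param seed Integer seed for the annealer.
#' @param control Passed to [simulated_annealing()].
#' @param polish Run the L-BFGS-B refinement after annealing (default
#'   `TRUE`).
#' @return A `biokin_fit`: best [parameter_set], WRSS, N, K,
#'   goodness-of-fit WRSS/(N-K), AICc, annealing trace and seed.
#' @export
fit_full_model <- function(dataset, structure, lambda = decay_constant("I131"),
                           init = NULL, constraints = fit_constraints(),
                           ref_blood_fractions = NULL,
                           seed = 1L, control = list(), polish = TRUE) {
  ev <- make_wrss_evaluator(dataset, structure, lambda)
  if (length(ev$skipped))
    warning("no data for organ(s): ", paste(ev$skipped, collapse = ", "),
            "; excluded from the objective")
  nr <- length(ev$rate_names)
  bf_names <- ev$bf_names
  ref <- ref_blood_fractions %||%
    (if (!is.null(dataset$ref_blood_fractions)) {
      # dataset table is keyed by organ in percent; remap to parameter names
      key <- vapply(structure$observations, function(o)
        as.character(o$blood_fraction %||% NA), character(1))
      stats::setNames(dataset$ref_blood_fractions[names(key)] / 100,
                      unname(key))[!is.na(key)]
    } else clr_reference_blood_fractions())
  bfb <- if (length(bf_names)) bf_bounds(bf_names, ref, constraints$bf_window)
  lower <- c(rep(constraints$rate_lower, nr), bfb$lower)
  upper <- c(rep(constraints$rate_upper, nr), bfb$upper)
  if (is.null(init)) {
    start <- c(rep(sqrt(constraints$rate_lower * constraints$rate_upper), nr),
               bfb$ref)
  } else {
    start <- c(init$rates[ev$rate_names],
               if (length(bf_names)) init$blood_fractions[bf_names])
    start <- pmin(pmax(start, lower), upper)
  }
  log_space <- c(rep(TRUE, nr), rep(FALSE, length(bf_names)))
  obj_resid <- function(theta) ev$resid(theta[seq_len(nr)],
                                        stats::setNames(theta[-seq_len(nr)],
                                                        bf_names))
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
  params <- parameter_set(stats::setNames(best$par[seq_len(nr)], ev$rate_names),
                          stats::setNames(best$par[-seq_len(nr)], bf_names),
                          lambda)
  new_fit_result(params, best$value, N = ev$n_points,
                 K = nr + length(bf_names), trace = sa$trace, seed = seed,
                 evaluations = sa$evaluations)
}

#' Predicted organ activities for a dataset's time points
#'
#' @inheritParams fit_full_model
#' @param params A [parameter_set].
#' @return The dataset's points with a `predicted` column.
#' @export
predict_dataset <- function(dataset, structure, params) {
  check_params(structure, params)
  p <- dataset$points
  organs <- intersect(names(structure$observations), unique(p$organ))
  p <- p[p$organ %in% organs, , drop = FALSE]
  times <- sort(unique(p$time_h))
  traj <- solve_activities(structure, params, times)
  p$predicted <- NA_real_
  for (org in organs) {
    a <- organ_activity(traj, structure, params, org)
    rows <- p$organ == org
    p$predicted[rows] <- a[match(p$time_h[rows], traj$times)]
  }
  p
}

#' WRSS of a parameter set against a dataset
#'
#' @inheritParams predict_dataset
#' @return Scalar WRSS over all points of observed organs.
#' @export
dataset_wrss <- function(dataset, structure, params) {
  p <- predict_dataset(dataset, structure, params)
  wrss(p$value, p$predicted, p$sigma)
}
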