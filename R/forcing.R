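#' Biexponential blood forcing function
#'
#' During decoupling the blood time-activity curve is frozen to an
#' analytic biexponential, \eqn{h(t) = A_1 e^{-\alpha_1 t} + A_2
#' e^{-\alpha_2 t}}, which then drives each organ subsystem as a fixed
#' input rather than a state.
#'
#' @param A1,A2 Amplitudes \[%\]; their sum is the activity in blood at
#'   t = 0 (100% for a bolus).
#' @param alpha1,alpha2 Decay rates \[h^-1\], > 0. Fitted on
#'   decay-included data they absorb the physical decay.
#' @return Object of class `forcing_function`; callable via
#'   [eval_forcing()].
#' @export
forcing_function <- function(A1, A2, alpha1, alpha2) {
  if (alpha1 <= 0 || alpha2 <= 0) stop("forcing rates must be positive")
  out <- list(A1 = A1, A2 = A2, alpha1 = alpha1, alpha2 = alpha2)
  class(out) <- "forcing_function"
  out
}

#' @rdname forcing_function
#' @param ff A `forcing_function`.
#' @param t Times \[h\].
#' @export
eval_forcing <- function(ff, t) {
  ff$A1 * exp(-ff$alpha1 * t) + ff$A2 * exp(-ff$alpha2 * t)
}

#' @export
print.forcing_function <- function(x, ...) {
  cat("<forcing_function> ", signif(x$A1, 4), " exp(-", signif(x$alpha1, 4),
      " t) + ", signif(x$A2, 4), " exp(-", signif(x$alpha2, 4), " t)\n",
      sep = "")
  invisible(x)
}

#' Fit the blood forcing function
#'
#' Weighted least-squares biexponential fit of the blood series with the
#' amplitude sum constrained to the injected activity (100% by default):
#' the amplitudes are parameterized as \eqn{A_1 = c p}, \eqn{A_2 =
#' c(1-p)} with \eqn{p \in [0,1]}. A Levenberg-Marquardt refinement
#' follows a coarse grid/heuristic start.
#'
#' @param blood_series Data frame with `time_h`, `value` and optionally
#'   `sigma` (inverse-variance weights), or a [biokin_dataset] whose
#'   `blood` series is used. At least 4 points.
#' @param total Activity at t = 0 \[%\]; default 100.
#' @return A [forcing_function] with attributes `wrss` and `n`.
#' @export
fit_forcing_function <- function(blood_series, total = 100) {
  s <- blood_series
  if (inherits(s, "biokin_dataset"))
    s <- s$points[s$points$organ == "blood", , drop = FALSE]
  if (nrow(s) < 4)
    stop("need at least 4 blood points for a biexponential fit")
  t <- s$time_h; a <- s$value
  w <- if (!is.null(s$sigma) && all(is.finite(s$sigma)) && all(s$sigma > 0))
    1 / s$sigma^2 else rep(1, length(a))
  # heuristic start: slow rate from the late tail, fast rate a decade above
  tail_idx <- t >= stats::median(t)
  sl <- stats::lm(log(pmax(a[tail_idx], 1e-12)) ~ t[tail_idx])
  a2_0 <- max(-stats::coef(sl)[[2]], 1e-4)
  start <- list(p = 0.6, l1 = log(max(a2_0 * 20, 1e-3)), l2 = log(a2_0))
  df <- data.frame(t = t, a = a)
  fit <- try(minpack.lm::nlsLM(
    a ~ total * (p * exp(-exp(l1) * t) + (1 - p) * exp(-exp(l2) * t)),
    data = df, start = start, weights = w,
    lower = c(p = 0, l1 = log(1e-6), l2 = log(1e-6)),
    upper = c(p = 1, l1 = log(1e3), l2 = log(1e3)),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    obj <- function(th) sum(w * (a - total * (th[1] * exp(-exp(th[2]) * t) +
                                   (1 - th[1]) * exp(-exp(th[3]) * t)))^2)
    op <- stats::optim(unlist(start), obj, method = "L-BFGS-B",
                       lower = c(0, log(1e-6), log(1e-6)),
                       upper = c(1, log(1e3), log(1e3)))
    cf <- op$par; rss <- op$value
  } else {
    cf <- stats::coef(fit)
    res <- a - stats::predict(fit)
    rss <- sum(w * res^2)
  }
  p <- cf[[1]]; r1 <- exp(cf[[2]]); r2 <- exp(cf[[3]])
  # order so alpha1 is the fast rate
  if (r1 < r2) { p <- 1 - p; tmp <- r1; r1 <- r2; r2 <- tmp }
  if (abs(r1 - r2) / max(r1, r2) < 1e-3)
    warning("biexponential rates nearly coincide; ",
            "blood data may be single-exponential")
  ff <- forcing_function(total * p, total * (1 - p), r1, r2)
  attr(ff, "wrss") <- rss
  attr(ff, "n") <- length(a)
  ff
}

# matrix, initial state and observable weights of a blood-locked
# subsystem: blood is replaced by the two forcing exponentials
forced_system <- function(variant_structure, forcing, rates, lambda,
                          organ, blood_fraction = NA_real_) {
  st <- variant_structure
  tissue <- setdiff(st$compartments, "blood")
  states <- c("u1", "u2", tissue)
  n <- length(states)
  A <- matrix(0, n, n, dimnames = list(states, states))
  A["u1", "u1"] <- -forcing$alpha1
  A["u2", "u2"] <- -forcing$alpha2
  for (r in seq_len(nrow(st$edges))) {
    from <- st$edges$from[r]; to <- st$edges$to[r]
    k <- rates[[st$edges$rate[r]]]
    if (from == "blood") {
      A[to, "u1"] <- A[to, "u1"] + k
      A[to, "u2"] <- A[to, "u2"] + k
    } else if (to == "blood") {
      A[from, from] <- A[from, from] - k
    } else {
      A[to, from] <- A[to, from] + k
      A[from, from] <- A[from, from] - k
    }
  }
  for (cmp in tissue) A[cmp, cmp] <- A[cmp, cmp] - lambda
  y0 <- stats::setNames(numeric(n), states)
  y0["u1"] <- forcing$A1; y0["u2"] <- forcing$A2
  ob <- st$observations[[organ]]
  w <- stats::setNames(numeric(n), states)
  w[ob$compartments] <- 1
  if (!is.na(ob$blood_fraction) && is.finite(blood_fraction)) {
    w["u1"] <- w["u1"] + blood_fraction
    w["u2"] <- w["u2"] + blood_fraction
  }
  list(A = A, y0 = y0, w = w, states = states)
}

#' Fit one organ subsystem under a blood forcing function
#'
#' The decoupling stage: the blood state is locked to the fitted
#' biexponential and the candidate subsystem (one or two tissue
#' compartments) is fitted to a single organ series. The tissue states
#' obey \eqn{dy/dt = k_{in} h(t) - (\text{outflow} + \lambda) y} with
#' \eqn{h} the forcing input; the observed activity adds the organ's
#' blood-fraction share of \eqn{h}.
#'
#' @param forcing A [forcing_function], typically from
#'   [fit_forcing_function()].
#' @param organ_series Data frame with `time_h`, `value`, `sigma` for
#'   one organ, or a [biokin_dataset] (the named organ is used).
#' @param variant A candidate variant from [enumerate_variants()] or a
#'   bare [model_structure] containing `"blood"` plus tissue
#'   compartments and exactly one observed organ.
#' @param organ Organ label(s); defaults to every organ of the
#'   variant's observation map with data (the excretion schemes fit the
#'   kidneys and bladder-content series jointly).
#' @param ref_blood_fraction Named vector of reference blood fractions
#'   (as fractions) keyed by blood-fraction parameter name (a bare
#'   scalar is accepted for a single-organ variant), each bounded to
#'   the +/- window during fitting; `NULL` when no organ has a
#'   blood-fraction slot.
#' @param constraints A [fit_constraints].
#' @param lambda Physical decay constant \[h^-1\].
#' @param seed,control,polish Passed to the optimizer as in
#'   [fit_full_model()].
#' @return A `biokin_fit`; `$params` holds the subsystem rates (and
#'   blood fraction), `$tag` the variant provenance tag.
#' @export
fit_subsystem <- function(forcing, organ_series, variant, organ = NULL,
                          ref_blood_fraction = NULL,
                          constraints = fit_constraints(),
                          lambda = decay_constant("I131"),
                          seed = 1L, control = list(), polish = TRUE) {
  if (!inherits(forcing, "forcing_function"))
    stop("a fitted forcing function is required before subsystem fitting")
  tag <- NULL
  st <- variant
  if (!inherits(variant, "model_structure")) {
    st <- variant$structure; tag <- variant$tag
  }
  s <- organ_series
  if (inherits(s, "biokin_dataset")) {
    if (is.null(organ))
      organ <- intersect(names(st$observations), unique(s$points$organ))
    s <- s$points[s$points$organ %in% organ, , drop = FALSE]
  } else if (is.null(organ)) organ <- names(st$observations)[1]
  if (!nrow(s)) stop("no data points for organ(s) ",
                     paste(organ, collapse = ", "))
  if (any(!is.finite(s$sigma) | s$sigma <= 0))
    stop("organ series needs positive sigma")
  if (is.null(s$organ)) s$organ <- organ[1]
  rate_names <- st$edges$rate
  nr <- length(rate_names)
  bf_names <- unique(stats::na.omit(vapply(st$observations[organ], function(o)
    as.character(o$blood_fraction %||% NA), character(1))))
  if (!is.null(ref_blood_fraction) && is.null(names(ref_blood_fraction)) &&
      length(bf_names) == 1)
    names(ref_blood_fraction) <- bf_names
  bf_names <- intersect(bf_names, names(ref_blood_fraction))
  nb <- length(bf_names)
  refb <- if (nb) unlist(ref_blood_fraction)[bf_names]
  lower <- c(rep(constraints$rate_lower, nr),
             if (nb) pmax(refb * (1 - constraints$bf_window), 0))
  upper <- c(rep(constraints$rate_upper, nr),
             if (nb) pmin(refb * (1 + constraints$bf_window), 1))
  log_space <- c(rep(TRUE, nr), rep(FALSE, nb))
  start <- c(rep(sqrt(constraints$rate_lower * constraints$rate_upper), nr),
             refb)
  tt <- sort(unique(s$time_h))
  obj_resid <- function(theta) {
    rates <- stats::setNames(theta[seq_len(nr)], rate_names)
    bfs <- if (nb) stats::setNames(theta[nr + seq_len(nb)], bf_names)
    res <- numeric(0)
    sys0 <- forced_system(st, forcing, rates, lambda, organ[1])
    Y <- expm_action(sys0$A, sys0$y0, tt)  # shared state solution
    for (org in organ) {
      ob <- st$observations[[org]]
      w <- stats::setNames(numeric(length(sys0$states)), sys0$states)
      w[ob$compartments] <- 1
      if (!is.na(ob$blood_fraction) && ob$blood_fraction %in% bf_names)
        w[c("u1", "u2")] <- w[c("u1", "u2")] + bfs[[ob$blood_fraction]]
      rows <- s$organ == org
      pred <- as.numeric(Y %*% w)[match(s$time_h[rows], tt)]
      res <- c(res, (s$value[rows] - pred) / s$sigma[rows])
    }
    res
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
  params <- parameter_set(stats::setNames(best$par[seq_len(nr)], rate_names),
                          if (nb) stats::setNames(best$par[nr + seq_len(nb)],
                                                  bf_names) else numeric(),
                          lambda)
  new_fit_result(params, best$value, N = nrow(s), K = nr + nb,
                 trace = sa$trace, seed = seed, evaluations = sa$evaluations,
                 extra = list(tag = tag, organ = organ, forcing = forcing))
}
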