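#' Reduce the full model to one compartment per organ
#'
#' The "SM" simplification: slow tissue compartments and all their
#' edges are removed for every organ except the remaining-tissues pool
#' and the tumor, whose slow kinetics dominate their curves. The
#' observation map is updated accordingly.
#'
#' @param full A [model_structure] with `*_slow` compartments.
#' @param keep Slow compartments to retain; default `tumor_slow` and
#'   `rt_slow`.
#' @return The reduced [model_structure].
#' @export
simplify_structure <- function(full, keep = c("tumor_slow", "rt_slow")) {
  drop <- setdiff(grep("_slow$", full$compartments, value = TRUE), keep)
  if (!length(drop)) return(full)
  comps <- setdiff(full$compartments, drop)
  edges <- full$edges[!(full$edges$from %in% drop |
                          full$edges$to %in% drop), , drop = FALSE]
  obs <- lapply(full$observations, function(o) {
    o$compartments <- setdiff(o$compartments, drop)
    o
  })
  model_structure(comps, edges, obs)
}

#' Cumulated activity from a biexponential fit
#'
#' Fits \eqn{c_1 e^{-\mu_1 t} + c_2 e^{-\mu_2 t}} to a decay-included
#' series by weighted least squares and integrates it analytically:
#' \eqn{\tilde A = c_1/\mu_1 + c_2/\mu_2}. Rates are left unconstrained
#' so that rising series (bladder-like) are detected: a non-positive
#' fitted rate makes the integral divergent and `A_tilde` is returned
#' as `NA` with `divergent = TRUE`.
#'
#' @param series Data frame with `time_h`, `value` (> 0) and optionally
#'   `sigma`.
#' @param times Optional subset of acquisition times to fit on (e.g.
#'   `c(2, 24, 120, 505)`, the best four-point protocol); default all
#'   points. At least 4 points.
#' @return List with `c1`, `c2`, `mu1`, `mu2`, `A_tilde` \[%·h\],
#'   `wrss` on the fitted points, and `divergent`.
#' @export
biexp_cumact <- function(series, times = NULL) {
  s <- as.data.frame(series)
  if (!is.null(times)) {
    idx <- vapply(times, function(t0) {
      j <- which.min(abs(s$time_h - t0))
      if (abs(s$time_h[j] - t0) > 1e-6)
        stop("no data point at requested time ", t0, " h")
      j
    }, integer(1))
    s <- s[idx, , drop = FALSE]
  }
  if (nrow(s) < 4) stop("need at least 4 points for a biexponential fit")
  if (any(s$value <= 0)) stop("activities must be positive")
  t <- s$time_h; a <- s$value
  w <- if (!is.null(s$sigma) && all(is.finite(s$sigma)) && all(s$sigma > 0))
    1 / s$sigma^2 else rep(1, length(a))
  late <- t >= stats::median(t)
  sl <- stats::lm(log(a[late]) ~ t[late])
  mu2_0 <- -stats::coef(sl)[[2]]
  c2_0 <- exp(stats::coef(sl)[[1]])
  start <- list(c1 = max(a[1] - c2_0, 0.1 * a[1]),
                c2 = max(c2_0, 1e-6),
                mu1 = max(abs(mu2_0) * 20, 1e-2), mu2 = mu2_0)
  df <- data.frame(t = t, a = a)
  fit <- try(minpack.lm::nlsLM(
    a ~ c1 * exp(-mu1 * t) + c2 * exp(-mu2 * t), data = df,
    start = start, weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    obj <- function(th) sum(w * (a - th[1] * exp(-th[3] * t) -
                                   th[2] * exp(-th[4] * t))^2)
    op <- stats::optim(unlist(start), obj,
                       control = list(maxit = 5000, reltol = 1e-12))
    cf <- stats::setNames(op$par, c("c1", "c2", "mu1", "mu2"))
    rss <- op$value
  } else {
    cf <- stats::coef(fit)
    rss <- sum(w * (a - stats::predict(fit))^2)
  }
  if (cf[["mu1"]] < cf[["mu2"]]) # order fast first
    cf <- cf[c("c2", "c1", "mu2", "mu1")]
  divergent <- cf[[3]] <= 0 || cf[[4]] <= 0
  A_tilde <- if (divergent) NA_real_ else cf[[1]] / cf[[3]] + cf[[2]] / cf[[4]]
  list(c1 = cf[[1]], c2 = cf[[2]], mu1 = cf[[3]], mu2 = cf[[4]],
       A_tilde = A_tilde, wrss = rss, divergent = divergent)
}

#' Search for the best four-point acquisition protocol
#'
#' Exhaustively fits a biexponential to every combination of `n` times
#' from the series' grid and scores each by the WRSS of the fitted
#' curve against the full series.
#'
#' @inheritParams biexp_cumact
#' @param n Points per subset; default 4.
#' @return Data frame of subsets (times, full-series WRSS, `A_tilde`),
#'   best first; divergent fits are dropped.
#' @export
best_biexp_subset <- function(series, n = 4) {
  s <- as.data.frame(series)
  combos <- utils::combn(sort(unique(s$time_h)), n, simplify = FALSE)
  rows <- lapply(combos, function(ts) {
    fit <- try(biexp_cumact(s, times = ts), silent = TRUE)
    if (inherits(fit, "try-error") || fit$divergent) return(NULL)
    pred <- fit$c1 * exp(-fit$mu1 * s$time_h) + fit$c2 * exp(-fit$mu2 * s$time_h)
    w <- if (all(is.finite(s$sigma)) && all(s$sigma > 0)) 1 / s$sigma^2 else 1
    data.frame(times = paste(ts, collapse = ","),
               wrss_full = sum(w * (s$value - pred)^2),
               A_tilde = fit$A_tilde, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$wrss_full), , drop = FALSE]
}

#' Cumulated activity from a single measurement
#'
#' The crudest estimator: assume the activity follows pure physical
#' decay through the single measured point, \eqn{A(t) = A^* e^{-\lambda
#' (t - t^*)}}, and integrate from zero:
#' \eqn{\tilde A = A^* e^{\lambda t^*} / \lambda}. Set `from =
#' "t_star"` to integrate from the measurement time instead
#' (\eqn{A^*/\lambda}).
#'
#' @param t_star Measurement time \[h\].
#' @param A_star Measured activity \[%\], > 0.
#' @param lambda Physical decay constant \[h^-1\], > 0.
#' @param from Lower integration limit convention.
#' @return Cumulated activity \[%·h\].
#' @export
monoexp_cumact <- function(t_star, A_star, lambda,
                           from = c("zero", "t_star")) {
  from <- match.arg(from)
  if (lambda <= 0) stop("lambda must be positive; the integral diverges")
  if (A_star <= 0) stop("A_star must be positive")
  if (from == "zero") A_star * exp(lambda * t_star) / lambda
  else A_star / lambda
}

#' Relative cumulated-activity differences against a reference
#'
#' Tabulates \eqn{100 (\tilde A_{simpl} - \tilde A)/\tilde A} per organ
#' for each simplification. Organs missing from a simplification (e.g.
#' a divergent biexponential fit) get `NA`, flagged rather than
#' erroring.
#'
#' @param reference Named numeric vector of reference cumulated
#'   activities \[%·h\].
#' @param simplifications Named list of named numeric vectors on the
#'   same organ set (possibly partial).
#' @return Data frame: `organ`, `A_tilde`, one percent-difference
#'   column per simplification.
#' @export
compare_cumulated <- function(reference, simplifications) {
  organs <- names(reference)
  out <- data.frame(organ = organs, A_tilde = unname(reference),
                    stringsAsFactors = FALSE)
  for (nm in names(simplifications)) {
    v <- simplifications[[nm]][organs]
    out[[nm]] <- 100 * (unname(v) - unname(reference)) / unname(reference)
  }
  out
}
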