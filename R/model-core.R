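#' Build the rate matrix of the linear kinetic system
#'
#' The compartmental model is the constant-coefficient linear system
#' \eqn{dy/dt = M y}, where the off-diagonal entry `M[j, i]` is the rate
#' constant of the edge i -> j and the diagonal collects the negative sum
#' of each compartment's outgoing rates plus the physical decay constant.
#' Column sums therefore equal \eqn{-\lambda} exactly: material leaves
#' the system only by radioactive decay (and through sink edges, which
#' are ordinary edges into sink compartments).
#'
#' @param structure A [model_structure].
#' @param params A [parameter_set] providing a value for every edge.
#' @return Square numeric matrix \[h^-1\] with compartment dimnames.
#' @examples
#' m <- clr_final_model()
#' M <- build_rate_matrix(m, clr_reference_parameters())
#' range(colSums(M) + clr_reference_parameters()$lambda)  # ~0
#' @export
build_rate_matrix <- function(structure, params) {
  check_params(structure, params)
  comp <- structure$compartments
  n <- length(comp)
  M <- matrix(0, n, n, dimnames = list(comp, comp))
  if (nrow(structure$edges)) {
    k <- params$rates[structure$edges$rate]
    for (r in seq_len(nrow(structure$edges))) {
      i <- structure$edges$from[r]
      j <- structure$edges$to[r]
      M[j, i] <- M[j, i] + k[r]
      M[i, i] <- M[i, i] - k[r]
    }
  }
  diag(M) <- diag(M) - params$lambda
  M
}

# action of expm(M t) on y0 for a vector of times (rows of the result);
# eigendecomposition, vectorized over times, with a scaling-and-squaring
# fallback for (near-)defective matrices
expm_action <- function(M, y0, times) {
  eg <- eigen(M)
  cvec <- try(solve(eg$vectors, as.complex(y0)), silent = TRUE)
  if (!inherits(cvec, "try-error") && rcond_ok(eg$vectors)) {
    E <- exp(outer(eg$values, times))          # n x T
    return(t(Re(eg$vectors %*% (E * as.vector(cvec)))))
  }
  out <- matrix(0, length(times), nrow(M))
  for (ti in seq_along(times))
    out[ti, ] <- expm_series(M, times[ti]) %*% y0
  out
}

rcond_ok <- function(V) {
  rc <- try(rcond(rbind(cbind(Re(V), -Im(V)), cbind(Im(V), Re(V)))),
            silent = TRUE)
  !inherits(rc, "try-error") && is.finite(rc) && rc > 1e-13
}

# scaling-and-squaring Taylor evaluation of expm(M t); also serves as an
# independent slow path
expm_series <- function(M, t) {
  A <- M * t
  nrmA <- max(colSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrmA, 1e-300))) + 1L)
  A <- A / 2^s
  E <- diag(nrow(A)) + A
  term <- A
  for (k in 2:30) {
    term <- term %*% A / k
    E <- E + term
    if (max(abs(term)) < 1e-16) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

default_y0 <- function(structure) {
  y0 <- stats::setNames(numeric(length(structure$compartments)),
                        structure$compartments)
  y0["blood"] <- 100
  y0
}

#' Solve compartment activities over time
#'
#' Solves \eqn{dy/dt = M y} exactly via the matrix exponential,
#' \eqn{y(t) = e^{Mt} y_0}. The default initial condition is the study's
#' bolus: 100% of the injected activity in blood at t = 0, all other
#' compartments empty.
#'
#' @param structure A [model_structure].
#' @param params A [parameter_set].
#' @param times Increasing vector of times \[h\]; t = 0 is prepended when
#'   absent.
#' @param y0 Optional named non-negative initial activities \[%\].
#' @return Object of class `trajectory`: list with `times` and an
#'   activity matrix `y` (times x compartments) in % injected activity.
#' @export
solve_activities <- function(structure, params, times, y0 = NULL) {
  check_params(structure, params)
  if (is.null(y0)) y0 <- default_y0(structure)
  y0 <- y0[structure$compartments]
  if (any(is.na(y0)) || any(y0 < 0))
    stop("y0 must be a non-negative vector over all compartments")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (times[1] > 0) times <- c(0, times)
  M <- build_rate_matrix(structure, params)
  if (any(!is.finite(M))) stop("non-finite rate matrix")
  y <- expm_action(M, y0, times)
  dimnames(y) <- list(NULL, structure$compartments)
  out <- list(times = times, y = y)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " times in [",
      min(x$times), ", ", max(x$times), "] h, ",
      ncol(x$y), " compartments\n", sep = "")
  invisible(x)
}

# weight vector over compartments for one observed organ:
# 1 on member compartments, f_s on blood
observable_weights <- function(structure, params, organ) {
  ob <- structure$observations[[organ]]
  if (is.null(ob)) stop("unknown organ: ", organ)
  w <- stats::setNames(numeric(length(structure$compartments)),
                       structure$compartments)
  w[ob$compartments] <- 1
  if (!is.na(ob$blood_fraction)) {
    f <- params$blood_fractions[[ob$blood_fraction]]
    w["blood"] <- w["blood"] + f
  }
  w
}

#' Organ/tissue observable from a solved trajectory
#'
#' The measured activity of organ s is the sum of its member-compartment
#' activities plus its blood-fraction share of the blood pool,
#' \eqn{A_s(t) = \sum_{i \in s} y_i(t) + f_s y_{blood}(t)}.
#'
#' @param traj A `trajectory` from [solve_activities()].
#' @param structure,params The model used to produce `traj`.
#' @param organ Organ label present in the structure's observation map.
#' @return Numeric vector of activities \[%\] at `traj$times`.
#' @export
organ_activity <- function(traj, structure, params, organ) {
  w <- observable_weights(structure, params, organ)
  as.numeric(traj$y %*% w)
}

#' Cumulated (time-integrated) activity
#'
#' For a strictly stable linear system the integral of the state over
#' \eqn{[0, \infty)} has the closed form \eqn{\int_0^\infty y\,dt =
#' -M^{-1} y_0}; organ cumulated activities apply the observable weights
#' (member compartments plus blood fraction) to that vector. This is the
#' dosimetric quantity usually denoted \eqn{\tilde A}, in %·h of the
#' injected activity.
#'
#' @inheritParams solve_activities
#' @param organ Organ label(s); default all observed organs.
#' @return Named numeric vector of cumulated activities \[%·h\].
#' @examples
#' cumulated_activity(clr_final_model(), clr_reference_parameters())
#' @export
cumulated_activity <- function(structure, params, organ = NULL, y0 = NULL) {
  check_params(structure, params)
  if (is.null(y0)) y0 <- default_y0(structure)
  y0 <- y0[structure$compartments]
  M <- build_rate_matrix(structure, params)
  ev <- eigen(M, only.values = TRUE)$values
  if (any(Re(ev) > -1e-14))
    stop("system is not strictly stable; cumulated activity diverges ",
         "(lambda = 0 with a closed system?)")
  integral <- solve(M, -y0)
  names(integral) <- structure$compartments
  if (is.null(organ)) organ <- names(structure$observations)
  out <- vapply(organ, function(org) {
    sum(observable_weights(structure, params, org) * integral)
  }, numeric(1))
  stats::setNames(out, organ)
}

#' Blood-fraction share of an organ's cumulated activity
#'
#' Fraction (in percent) of the organ's total time-integrated activity
#' contributed by its blood-fraction term,
#' \eqn{100 f_s \tilde y_{blood} / \tilde A_s}.
#'
#' @inheritParams cumulated_activity
#' @param organ Single organ label with a blood-fraction slot.
#' @return Percentage in \[0, 100\].
#' @export
blood_contribution_share <- function(structure, params, organ, y0 = NULL) {
  ob <- structure$observations[[organ]]
  if (is.null(ob)) stop("unknown organ: ", organ)
  if (is.na(ob$blood_fraction))
    stop("organ '", organ, "' has no blood-fraction term")
  if (is.null(y0)) y0 <- default_y0(structure)
  y0 <- y0[structure$compartments]
  M <- build_rate_matrix(structure, params)
  integral <- stats::setNames(solve(M, -y0), structure$compartments)
  f <- params$blood_fractions[[ob$blood_fraction]]
  total <- cumulated_activity(structure, params, organ, y0 = y0)
  100 * f * integral[["blood"]] / unname(total)
}
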