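#' Simulated annealing for bounded, strictly positive parameters
#'
#' A compact simulated-annealing optimizer tailored to kinetic rate
#' constants: proposals are Gaussian steps in log-space (linear space
#' for parameters flagged otherwise), reflected at the box bounds; the
#' temperature follows a geometric schedule and the chain restarts from
#' the best-so-far point at each temperature change. The initial
#' temperature, when not given, is set to the interquartile spread of
#' the objective over a random probe around the starting point, so
#' acceptance starts permissive regardless of the objective's scale.
#'
#' @param fn Objective to minimize; takes a numeric vector, returns a
#'   scalar (non-finite values are treated as +Inf).
#' @param par Numeric start vector, inside the bounds.
#' @param lower,upper Box bounds (finite; recycled).
#' @param log_space Logical (recycled): propose steps in log space for
#'   these coordinates. Requires positive bounds.
#' @param control List: `n_temps` (temperature levels, default 60),
#'   `steps` (proposals per level, 40), `cooling` (geometric factor,
#'   0.95), `t0` (initial temperature, default from the probe),
#'   `step_sd` (proposal SD at T0 in transformed units, 0.4).
#' @param seed Integer seed; the run is fully reproducible given it.
#' @return List with `par`, `value`, `trace` (best objective per
#'   temperature level), `evaluations`, `seed`.
#' @export
simulated_annealing <- function(fn, par, lower, upper,
                                log_space = TRUE, control = list(),
                                seed = 1L) {
  ctl <- utils::modifyList(list(n_temps = 60L, steps = 40L, cooling = 0.95,
                                t0 = NULL, step_sd = 0.4), control)
  np <- length(par)
  lower <- rep_len(lower, np); upper <- rep_len(upper, np)
  log_space <- rep_len(log_space, np)
  if (any(lower > upper)) stop("lower > upper")
  if (any(log_space & lower <= 0))
    stop("log-space coordinates need positive lower bounds")
  if (any(par < lower | par > upper)) stop("start point outside bounds")
  tf  <- function(x) ifelse(log_space, log(x), x)
  itf <- function(z) ifelse(log_space, exp(z), z)
  lo <- tf(lower); hi <- tf(upper)
  reflect <- function(z) {
    span <- hi - lo
    zz <- ifelse(span <= 0, lo, {
      w <- (z - lo) %% (2 * span)
      lo + ifelse(w > span, 2 * span - w, w)
    })
    zz
  }
  set.seed(seed)
  nev <- 0L
  f <- function(z) {
    nev <<- nev + 1L
    v <- fn(itf(z))
    if (!is.finite(v)) Inf else v
  }
  z <- tf(par)
  fz <- f(z)
  if (!is.finite(fz)) stop("objective not finite at the start point")
  zbest <- z; fbest <- fz
  if (ctl$n_temps < 1L || ctl$steps < 1L)
    return(list(par = itf(zbest), value = fbest, trace = fbest,
                evaluations = nev, seed = seed))
  t0 <- ctl$t0
  if (is.null(t0)) {
    probe <- replicate(16, f(reflect(z + stats::rnorm(np, 0, ctl$step_sd))))
    probe <- probe[is.finite(probe)]
    t0 <- max(stats::IQR(c(probe, fz)), abs(fz) * 1e-3, 1e-8)
  }
  temp <- t0
  trace <- numeric(ctl$n_temps)
  for (lev in seq_len(ctl$n_temps)) {
    z <- zbest; fz <- fbest  # restart each level from the incumbent
    sd_lev <- ctl$step_sd * max(sqrt(temp / t0), 0.05)
    for (s in seq_len(ctl$steps)) {
      zp <- reflect(z + stats::rnorm(np, 0, sd_lev))
      fp <- f(zp)
      if (fp < fz || stats::runif(1) < exp(-(fp - fz) / temp)) {
        z <- zp; fz <- fp
        if (fz < fbest) { zbest <- z; fbest <- fz }
      }
    }
    trace[lev] <- fbest
    temp <- temp * ctl$cooling
  }
  list(par = itf(zbest), value = fbest, trace = trace,
       evaluations = nev, seed = seed)
}

# Levenberg-Marquardt refinement from the SA incumbent: all fit
# objectives here are weighted least squares, so the residual vector is
# polished in the same transformed (log for rates) space, bounds kept
polish_lm <- function(resid_fn, par, lower, upper, log_space,
                      maxiter = 200L) {
  np <- length(par)
  lower <- rep_len(lower, np); upper <- rep_len(upper, np)
  log_space <- rep_len(log_space, np)
  tf  <- function(x) ifelse(log_space, log(x), x)
  itf <- function(z) ifelse(log_space, exp(z), z)
  g <- function(z) {
    r <- resid_fn(itf(z))
    r[!is.finite(r)] <- 1e6
    r
  }
  res <- try(minpack.lm::nls.lm(tf(par), fn = g,
                                lower = tf(lower), upper = tf(upper),
                                control = minpack.lm::nls.lm.control(
                                  maxiter = maxiter, ftol = 1e-14,
                                  ptol = 1e-12)),
             silent = TRUE)
  if (inherits(res, "try-error"))
    return(list(par = par, value = sum(resid_fn(par)^2)))
  list(par = itf(res$par), value = res$deviance)
}
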