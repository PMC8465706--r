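#' Saltelli sampling design for Sobol indices
#'
#' Builds the two independent sample blocks A and B and the K cross
#' blocks AB_i (B's column i substituted into A) needed by the
#' Saltelli/Jansen estimators, for a total of M(K+2) model evaluations.
#' Parameters are perturbed around the base point with zero-mean normal
#' noise of relative standard deviation `rel_sd`, truncated below at 0
#' to respect rate positivity.
#'
#' @param base_params Named numeric vector: the base point (e.g. the
#'   best-fit rates and blood fractions).
#' @param M Samples per block, >= 2.
#' @param rel_sd Relative standard deviation of the perturbations; the
#'   study used 0.10.
#' @param seed Integer seed; the design is reproducible given it.
#' @return Object of class `sobol_design` with matrices `A`, `B` and
#'   the list `AB`.
#' @export
sobol_design <- function(base_params, M, rel_sd = 0.10, seed = 1L) {
  if (M < 2) stop("M must be >= 2")
  if (rel_sd <= 0) stop("rel_sd must be positive")
  base <- unlist(base_params)
  K <- length(base)
  if (is.null(names(base))) names(base) <- paste0("p", seq_len(K))
  set.seed(seed)
  draw <- function() {
    Z <- matrix(stats::rnorm(M * K), M, K)
    X <- sweep(sweep(Z, 2, rel_sd * base, `*`), 2, base, `+`)
    X[X < 0] <- 0
    colnames(X) <- names(base)
    X
  }
  A <- draw(); B <- draw()
  AB <- lapply(seq_len(K), function(i) { X <- A; X[, i] <- B[, i]; X })
  names(AB) <- names(base)
  out <- list(A = A, B = B, AB = AB, M = M, K = K, rel_sd = rel_sd,
              base = base, seed = seed)
  class(out) <- "sobol_design"
  out
}

#' @export
print.sobol_design <- function(x, ...) {
  cat("<sobol_design> K = ", x$K, ", M = ", x$M, ": ",
      x$M * (x$K + 2), " evaluations\n", sep = "")
  invisible(x)
}

#' First- and total-order Sobol indices
#'
#' Variance-based sensitivity of a scalar model output (by default the
#' WRSS against the reference dataset) with respect to each parameter.
#' Jansen estimators are used: \eqn{S_i = (V - \frac{1}{2M}\sum (f_B -
#' f_{AB_i})^2)/V} and \eqn{S_{T,i} = \frac{1}{2M}\sum (f_A -
#' f_{AB_i})^2 / V}. First-order indices measure a parameter's direct
#' effect; total-order indices include all interactions, so
#' \eqn{S_{T,i} \approx 0} marks a parameter that can be pruned.
#'
#' @param evaluator Function: named parameter vector -> finite scalar.
#'   Non-finite outputs are masked with a warning.
#' @param design A [sobol_design].
#' @return Object of class `sobol_result`: data frame `indices` with
#'   columns `parameter`, `S`, `ST`, `se_S`, `se_ST` (Monte Carlo
#'   standard errors), plus `n_masked`.
#' @export
sobol_indices <- function(evaluator, design) {
  eval_block <- function(X)
    vapply(seq_len(nrow(X)), function(r) evaluator(X[r, ]), numeric(1))
  fA <- eval_block(design$A)
  fB <- eval_block(design$B)
  fAB <- vapply(design$AB, eval_block, numeric(design$M))
  ok <- is.finite(fA) & is.finite(fB) & apply(is.finite(fAB), 1, all)
  n_masked <- sum(!ok)
  if (n_masked) {
    warning(n_masked, " non-finite evaluation row(s) masked")
    fA <- fA[ok]; fB <- fB[ok]; fAB <- fAB[ok, , drop = FALSE]
  }
  M <- length(fA)
  V <- stats::var(c(fA, fB))
  S <- ST <- se_S <- se_ST <- numeric(design$K)
  for (i in seq_len(design$K)) {
    d1 <- (fB - fAB[, i])^2 / 2   # E[d1] = V - V_i
    dT <- (fA - fAB[, i])^2 / 2   # E[dT] = V_Ti
    S[i] <- (V - mean(d1)) / V
    ST[i] <- mean(dT) / V
    se_S[i] <- stats::sd(d1) / sqrt(M) / V
    se_ST[i] <- stats::sd(dT) / sqrt(M) / V
  }
  out <- list(indices = data.frame(parameter = names(design$base),
                                   S = S, ST = ST, se_S = se_S,
                                   se_ST = se_ST,
                                   stringsAsFactors = FALSE),
              variance = V, M = M, n_masked = n_masked, seed = design$seed)
  class(out) <- "sobol_result"
  out
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("<sobol_result> M = ", x$M, ", output variance = ",
      signif(x$variance, 4), "\n", sep = "")
  print(transform(x$indices, S = signif(S, 3), ST = signif(ST, 3),
                  se_S = signif(se_S, 2), se_ST = signif(se_ST, 2)))
  invisible(x)
}

#' Parameters removable on sensitivity grounds
#'
#' A parameter whose total-order index is indistinguishable from zero
#' affects the objective neither directly nor through interactions and
#' can be omitted from the model. The test is `ST - se_ST < threshold`.
#'
#' @param result A [sobol_indices()] result.
#' @param threshold Non-negative cutoff on the total-order index;
#'   default 0.01.
#' @return Character vector of prunable parameter names.
#' @export
prune_parameters <- function(result, threshold = 0.01) {
  if (threshold < 0) stop("threshold must be >= 0")
  idx <- result$indices
  prune <- idx$parameter[idx$ST - idx$se_ST < threshold]
  if (length(prune))
    message("prunable (ST ~ 0): ", paste(prune, collapse = ", "))
  prune
}
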