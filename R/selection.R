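#' Corrected Akaike Information Criterion
#'
#' Small-sample AIC used to rank candidate model structures,
#' \eqn{AICc = N \ln(WRSS/N) + 2K + 2K(K+1)/(N-K-1)}; models with lower
#' AICc are preferred. The logarithm is natural (standard AIC
#' convention; configurable via `base`).
#'
#' @param wrss_value Positive objective value.
#' @param N Number of data points.
#' @param K Number of model parameters (rate constants plus blood
#'   fractions).
#' @param base Logarithm base; default `exp(1)`.
#' @return Scalar AICc.
#' @examples
#' aicc(2, 10, 3)  # 10*log(0.2) + 6 + 4
#' @export
aicc <- function(wrss_value, N, K, base = exp(1)) {
  if (N <= K + 1)
    stop("AICc undefined: need N > K + 1 (N = ", N, ", K = ", K, ")")
  if (wrss_value <= 0) stop("WRSS must be positive")
  N * log(wrss_value / N, base = base) + 2 * K + 2 * K * (K + 1) / (N - K - 1)
}

variant <- function(tag, structure, zeroed = character()) {
  out <- list(tag = tag, structure = structure, zeroed = zeroed)
  class(out) <- "candidate_variant"
  out
}

#' @export
print.candidate_variant <- function(x, ...) {
  cat("<candidate_variant> ", x$tag, ": ", nrow(x$structure$edges),
      " free rates", if (length(x$zeroed))
        paste0(" (zeroed: ", paste(x$zeroed, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Candidate subsystem structures for one organ or for excretion
#'
#' For an ordinary organ, the four candidate subsystems considered
#' during decoupling: a single tissue compartment with bidirectional
#' blood exchange or as a sink, and a fast/slow two-compartment tissue
#' with all four rates or with the slow pool a sink. For the excreted
#' activity, the two schemes considered: bladder contents fed from the
#' kidney fast pool and/or directly from blood (with single-edge
#' removals), and a urinary-path scheme where activity transits an
#' intermediate compartment between blood and bladder (with and without
#' a return to blood).
#'
#' @param organ Organ label; the observed organ of every returned
#'   variant.
#' @param excretion If `TRUE`, return the excretion variants (the
#'   `organ` argument then labels the bladder-contents series and the
#'   kidneys series is fitted alongside).
#' @param blood_fraction_name Name of the blood-fraction parameter used
#'   in the observation map (`NA` for organs with negligible blood
#'   content, e.g. the tumor).
#' @return List of candidate variants (tag, structure, zeroed rates).
#' @export
enumerate_variants <- function(organ, excretion = FALSE,
                               blood_fraction_name = paste0("f_", organ)) {
  if (!excretion) {
    one <- function(tag, edges, zeroed = character(), two_comp = FALSE) {
      comps <- c("blood", if (two_comp) c("fast", "slow") else "tissue")
      obs <- stats::setNames(list(list(
        compartments = if (two_comp) c("fast", "slow") else "tissue",
        blood_fraction = blood_fraction_name)), organ)
      variant(tag, model_structure(comps, edges, obs), zeroed)
    }
    e <- function(...) {
      m <- matrix(c(...), ncol = 2, byrow = TRUE)
      data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
    }
    return(list(
      one("1c_bidirectional", e("blood", "tissue", "tissue", "blood")),
      one("1c_sink", e("blood", "tissue"), zeroed = "k_tissue_blood"),
      one("2c_4rates", e("blood", "fast", "fast", "blood",
                         "fast", "slow", "slow", "fast"), two_comp = TRUE),
      one("2c_slow_sink", e("blood", "fast", "fast", "blood",
                            "fast", "slow"), zeroed = "k_slow_fast",
          two_comp = TRUE)
    ))
  }
  # excretion schemes; bladder contents are always observed with no
  # blood fraction, the kidneys observable rides along in scheme 1
  kid_obs <- list(
    kidneys = list(compartments = c("kidney_fast", "kidney_slow"),
                   blood_fraction = "f_kidneys"),
    bladder = list(compartments = "bladder", blood_fraction = NA))
  kid <- function(tag, drop = character()) {
    edges <- data.frame(
      from = c("blood", "kidney_fast", "kidney_fast", "kidney_fast",
               "kidney_slow", "blood"),
      to = c("kidney_fast", "blood", "kidney_slow", "bladder",
             "kidney_fast", "bladder"), stringsAsFactors = FALSE)
    edges$rate <- rate_name(edges$from, edges$to)
    keep <- !(edges$rate %in% drop)
    variant(tag, model_structure(c("blood", "kidney_fast", "kidney_slow",
                                   "bladder"), edges[keep, ], kid_obs),
            zeroed = drop)
  }
  # the urinary-path schemes keep the kidneys as an ordinary fast/slow
  # organ off the excretion path, so every excretion variant is fitted
  # to the same kidneys + bladder data and the AICc values compare
  upath <- function(tag, with_return) {
    edges <- data.frame(
      from = c("blood", "kidney_fast", "kidney_fast",
               "blood", "upath", if (with_return) "upath"),
      to = c("kidney_fast", "blood", "kidney_slow",
             "upath", "bladder", if (with_return) "blood"),
      stringsAsFactors = FALSE)
    variant(tag, model_structure(c("blood", "kidney_fast", "kidney_slow",
                                   "upath", "bladder"), edges, kid_obs),
            zeroed = if (!with_return) "k_upath_blood")
  }
  list(
    kid("kidney_path_full"),
    kid("kidney_path_no_blood_bladder", drop = "k_blood_bladder"),
    kid("kidney_path_no_slow_fast", drop = "k_kidney_slow_kidney_fast"),
    kid("kidney_path_minimal",
        drop = c("k_blood_bladder", "k_kidney_slow_kidney_fast")),
    upath("urinary_path_with_return", with_return = TRUE),
    upath("urinary_path_no_return", with_return = FALSE)
  )
}

#' Rank candidate fits and select the winning structure
#'
#' Returns the candidate with the smallest AICc; ties are broken by
#' smaller K, then by lexicographic tag. Results fitted to datasets of
#' different size are not comparable and trigger a warning.
#'
#' @param fit_results List of `biokin_fit` objects carrying `$aicc`,
#'   `$K` and a `$tag`.
#' @return List with `winner` (the selected fit), `ranking` (data frame
#'   with tag, WRSS, goodness-of-fit, AICc, K, sorted best first).
#' @export
select_structure <- function(fit_results) {
  if (!length(fit_results)) stop("no fit results supplied")
  Ns <- vapply(fit_results, `[[`, numeric(1), "N")
  if (length(unique(Ns)) > 1)
    warning("fits use datasets of different size (N = ",
            paste(unique(Ns), collapse = ", "), "); AICc not comparable")
  tab <- data.frame(
    tag = vapply(fit_results, function(f) f$tag %||% "<untagged>",
                 character(1)),
    wrss = vapply(fit_results, `[[`, numeric(1), "wrss"),
    gof = vapply(fit_results, `[[`, numeric(1), "gof"),
    aicc = vapply(fit_results, `[[`, numeric(1), "aicc"),
    K = vapply(fit_results, `[[`, numeric(1), "K"),
    stringsAsFactors = FALSE)
  ord <- order(tab$aicc, tab$K, tab$tag)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(winner = fit_results[[ord[1]]], ranking = tab)
}
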