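#' Serialize a model structure (and optional parameters) to JSON
#'
#' The config carries compartments, edges with their rate names (and
#' values when parameters are given), the observation map, the decay
#' constant and blood fractions — enough to rebuild the model exactly.
#'
#' @param structure A [model_structure].
#' @param path Output file.
#' @param params Optional [parameter_set] to embed.
#' @return `path`, invisibly.
#' @export
write_structure_json <- function(structure, path, params = NULL) {
  edges <- structure$edges
  if (!is.null(params)) edges$value <- unname(params$rates[edges$rate])
  obj <- list(compartments = structure$compartments,
              edges = edges,
              observations = lapply(structure$observations, function(o)
                list(compartments = o$compartments,
                     blood_fraction = if (is.na(o$blood_fraction)) NULL
                                      else o$blood_fraction)))
  if (!is.null(params)) {
    obj$lambda <- params$lambda
    obj$blood_fractions <- as.list(params$blood_fractions)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Rebuild a model structure (and parameters) from JSON
#'
#' @param path File written by [write_structure_json()].
#' @return List with `structure` and, when present in the file,
#'   `params`.
#' @export
read_structure_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  obs <- lapply(obj$observations, function(o)
    list(compartments = unlist(o$compartments),
         blood_fraction = o$blood_fraction %||% NA_character_))
  st <- model_structure(obj$compartments, obj$edges, obs)
  out <- list(structure = st)
  if (!is.null(obj$edges$value)) {
    out$params <- parameter_set(
      stats::setNames(obj$edges$value, obj$edges$rate),
      unlist(obj$blood_fractions) %||% numeric(),
      obj$lambda %||% 0)
  }
  out
}

#' Serialize a fit result to JSON
#'
#' @param fit A `biokin_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(rates = as.list(fit$params$rates),
              blood_fractions = as.list(fit$params$blood_fractions),
              lambda = fit$params$lambda,
              wrss = fit$wrss, N = fit$N, K = fit$K,
              goodness_of_fit = fit$gof, aicc = fit$aicc,
              seed = fit$seed, evaluations = fit$evaluations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# cheap polynomial rolling hash; provenance fingerprint for output files
config_fingerprint <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
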