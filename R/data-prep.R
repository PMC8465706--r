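#' Construct a time-activity dataset
#'
#' A dataset bundles the tidy table of measured points with the organ
#' masses and reference blood fractions needed for processing and
#' fitting. Points live in one data frame with one row per measurement.
#'
#' @param points Data frame with columns `organ`, `time_h`, `value`,
#'   `sigma` (may be `NA` before [assign_uncertainties()]), `modality`
#'   (`"PET"`, `"SPECT"`, `"blood"`, `"urine"` or `"synthetic"`),
#'   `units` (`"percent"` or `"percent_per_gram"`) and `decay`
#'   (`"decay_included"` or `"decay_corrected"`).
#' @param masses Named numeric vector of organ masses \[g\], or `NULL`.
#' @param ref_blood_fractions Named numeric vector of reference blood
#'   fractions \[%\] in \[0, 100\], or `NULL`.
#' @return An object of class `biokin_dataset`.
#' @export
biokin_dataset <- function(points, masses = NULL, ref_blood_fractions = NULL) {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  needed <- c("organ", "time_h", "value")
  if (!all(needed %in% names(points)))
    stop("points need columns: ", paste(needed, collapse = ", "))
  for (col in c("sigma")) if (is.null(points[[col]])) points[[col]] <- NA_real_
  if (is.null(points$modality)) points$modality <- "synthetic"
  if (is.null(points$units))    points$units    <- "percent"
  if (is.null(points$decay))    points$decay    <- "decay_included"
  if (any(points$time_h < 0)) stop("times must be >= 0")
  ord <- order(points$organ, points$time_h)
  points <- points[ord, , drop = FALSE]
  rownames(points) <- NULL
  if (!is.null(ref_blood_fractions) &&
      (any(ref_blood_fractions < 0) || any(ref_blood_fractions > 100)))
    stop("reference blood fractions must be percentages in [0, 100]")
  out <- list(points = points, masses = masses,
              ref_blood_fractions = ref_blood_fractions)
  class(out) <- "biokin_dataset"
  out
}

#' @export
print.biokin_dataset <- function(x, ...) {
  cat("<biokin_dataset> ", nrow(x$points), " points, ",
      length(unique(x$points$organ)), " series: ",
      paste(unique(x$points$organ), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convert activity concentrations to absolute activities
#'
#' Multiplies concentrations \[%/g\] by the organ mass \[g\] to obtain
#' relative activities \[%\]; uncertainties are scaled identically. Only
#' rows flagged `percent_per_gram` are touched.
#'
#' @param dataset A [biokin_dataset] whose `masses` (or the `masses`
#'   argument) provide a mass for every organ measured in %/g.
#' @param masses Optional named numeric vector overriding
#'   `dataset$masses`.
#' @return The dataset with those series expressed in percent.
#' @export
concentration_to_activity <- function(dataset, masses = NULL) {
  masses <- masses %||% dataset$masses
  p <- dataset$points
  idx <- which(p$units == "percent_per_gram")
  if (!length(idx)) return(dataset)
  for (org in unique(p$organ[idx])) {
    m <- masses[[org]] %||% NA_real_
    if (is.na(m) || m <= 0)
      stop("no positive mass available for organ '", org, "'")
    rows <- idx[p$organ[idx] == org]
    p$value[rows] <- p$value[rows] * m
    p$sigma[rows] <- p$sigma[rows] * m
    p$units[rows] <- "percent"
  }
  dataset$points <- p
  dataset
}

#' Merge PET and rescaled SPECT tumor series
#'
#' The tumor PET (early) and SPECT (late) series disagree in scale, so
#' the SPECT points are fitted to a single exponential by weighted least
#' squares on log-activities and rescaled so the fitted curve passes
#' through the PET value at the junction time. SPECT points at or before
#' the junction are discarded; the rescaled remainder is concatenated
#' after the PET series.
#'
#' @param pet_series,spect_series Data frames with `time_h`, `value` and
#'   optionally `sigma`.
#' @param junction_time_h Time \[h\] of the last PET point; default 120.
#' @return List with elements `merged` (data frame), `scale` and the
#'   exponential fit coefficients `A` and `mu`.
#' @export
merge_pet_spect_tumor <- function(pet_series, spect_series,
                                  junction_time_h = 120) {
  pet <- as.data.frame(pet_series)
  sp <- as.data.frame(spect_series)
  jrow <- which(abs(pet$time_h - junction_time_h) < 1e-9)
  if (!length(jrow))
    stop("PET series has no point at the junction time ", junction_time_h, " h")
  keep <- sp$time_h > junction_time_h + 1e-9
  if (sum(keep) < 2)
    stop("need at least two SPECT points after the junction time")
  dropped <- sum(!keep)
  sp_fit <- sp  # fit on all SPECT points, then keep only the late ones
  if (any(sp_fit$value <= 0)) stop("SPECT activities must be positive")
  w <- if (!is.null(sp_fit$sigma) && all(is.finite(sp_fit$sigma)))
    (sp_fit$value / sp_fit$sigma)^2 else rep(1, nrow(sp_fit))
  fit <- stats::lm(log(value) ~ time_h, data = sp_fit, weights = w)
  A <- exp(stats::coef(fit)[[1]])
  mu <- -stats::coef(fit)[[2]]
  scale <- pet$value[jrow[1]] / (A * exp(-mu * junction_time_h))
  sp_out <- sp[keep, , drop = FALSE]
  sp_out$value <- sp_out$value * scale
  if (!is.null(sp_out$sigma)) sp_out$sigma <- sp_out$sigma * scale
  merged <- rbind(pet[intersect(names(pet), names(sp_out))],
                  sp_out[intersect(names(pet), names(sp_out))])
  merged <- merged[order(merged$time_h), , drop = FALSE]
  rownames(merged) <- NULL
  list(merged = merged, scale = unname(scale), A = unname(A),
       mu = unname(mu), spect_points_dropped = dropped)
}

#' Assign relative measurement uncertainties
#'
#' Applies the study's uncertainty model: 5% of the measured activity
#' for every point, 10% for SPECT-derived tumor points (which carry the
#' PET/SPECT calibration mismatch). Points that already have a finite
#' sigma (e.g. cohort dispersions of blood and urine) are left alone.
#' Zero activities get a small floor so inverse-variance weights stay
#' finite.
#'
#' @param dataset A [biokin_dataset] in percent units.
#' @param rel Default relative uncertainty; 0.05.
#' @param tumor_spect_rel Relative uncertainty for tumor SPECT points;
#'   0.10.
#' @param sigma_floor Floor for zero activities; 1e-6 %.
#' @return The dataset with `sigma` filled in.
#' @export
assign_uncertainties <- function(dataset, rel = 0.05, tumor_spect_rel = 0.10,
                                 sigma_floor = 1e-6) {
  p <- dataset$points
  if (any(p$units != "percent"))
    stop("convert concentrations to percent before assigning uncertainties")
  todo <- !is.finite(p$sigma)
  r <- ifelse(p$organ == "tumor" & p$modality == "SPECT", tumor_spect_rel, rel)
  sig <- r * abs(p$value)
  zero <- todo & sig <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-activity point(s); sigma floor applied")
    sig[zero] <- sigma_floor
  }
  p$sigma[todo] <- sig[todo]
  dataset$points <- p
  dataset
}

#' Remove excluded points or series
#'
#' Applies the study's exclusion rules (e.g. the urine point at 120 h
#' whose cohort dispersion was unrepresentative, or the whole low-uptake
#' spinal-cord series).
#'
#' @param dataset A [biokin_dataset].
#' @param exclusions List of exclusions, each a list with `organ` and
#'   optionally `time_h` (omit to drop the whole series) and `reason`.
#' @return The filtered dataset; removals are reported via `message()`.
#' @export
filter_points <- function(dataset, exclusions = list()) {
  p <- dataset$points
  for (ex in exclusions) {
    if (is.null(ex$time_h)) {
      hit <- p$organ == ex$organ
    } else {
      hit <- p$organ == ex$organ & abs(p$time_h - ex$time_h) < 1e-9
    }
    if (!any(hit)) {
      warning("exclusion matched nothing: ", ex$organ,
              if (!is.null(ex$time_h)) paste0(" @ ", ex$time_h, " h"))
      next
    }
    message("excluding ", sum(hit), " point(s) for ", ex$organ,
            if (!is.null(ex$time_h)) paste0(" at ", ex$time_h, " h"),
            if (!is.null(ex$reason)) paste0(" (", ex$reason, ")"))
    p <- p[!hit, , drop = FALSE]
  }
  dataset$points <- p
  dataset
}

#' Read / write time-activity tables
#'
#' Tidy CSV with columns `organ`, `time_h`, `value`, `sigma`,
#' `modality`, `units`, `decay`.
#'
#' @param path File path.
#' @param dataset A [biokin_dataset].
#' @return `read_tac_csv()` returns a [biokin_dataset];
#'   `write_tac_csv()` returns `path` invisibly.
#' @export
read_tac_csv <- function(path) {
  biokin_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_tac_csv
#' @export
write_tac_csv <- function(dataset, path) {
  utils::write.csv(dataset$points, path, row.names = FALSE)
  invisible(path)
}
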