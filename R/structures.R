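#' Physical decay constants for the iodine theranostic pair
#'
#' Half-lives are conventional nuclide data: 8.0252 d for 131I and
#' 4.176 d for 124I. The decay constant is \eqn{\lambda = \ln 2 / T_{1/2}}
#' expressed per hour, the package's time unit.
#'
#' @param nuclide `"I131"` or `"I124"`, or a numeric half-life in days.
#' @return Decay constant \eqn{\lambda} in h^-1.
#' @examples
#' decay_constant("I131")
#' @export
decay_constant <- function(nuclide = "I131") {
  if (is.numeric(nuclide)) {
    t_half_days <- nuclide
  } else {
    t_half_days <- switch(match.arg(nuclide, c("I131", "I124")),
                          I131 = 8.0252, I124 = 4.176)
  }
  log(2) / (t_half_days * 24)
}

rate_name <- function(from, to) paste0("k_", from, "_", to)

#' Define a compartmental model structure
#'
#' A structure is the directed graph of the kinetic model: compartment
#' labels, transfer edges each bound to a named rate parameter, and an
#' observation map describing which compartments (plus an optional blood
#' fraction) make up each measurable organ/tissue.
#'
#' @param compartments Character vector of unique compartment ids. Must
#'   contain `"blood"`.
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `rate` (parameter name; defaults to `k_<from>_<to>`). Self-edges are
#'   not allowed.
#' @param observations Named list; one entry per observable organ, each a
#'   list with elements `compartments` (character vector, possibly empty)
#'   and `blood_fraction` (name of the blood-fraction parameter, or `NA`
#'   for organs whose blood content is negligible).
#' @return An object of class `model_structure`.
#' @seealso [clr_final_model()] for the published 17-compartment model.
#' @export
model_structure <- function(compartments, edges, observations = list()) {
  compartments <- as.character(compartments)
  if (anyDuplicated(compartments))
    stop("compartment ids must be unique")
  if (!"blood" %in% compartments)
    stop("a 'blood' compartment is required")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (!all(c("from", "to") %in% names(edges)))
      stop("edges need 'from' and 'to' columns")
    if (is.null(edges$rate)) edges$rate <- rate_name(edges$from, edges$to)
    bad <- !(edges$from %in% compartments) | !(edges$to %in% compartments)
    if (any(bad))
      stop("edge endpoints not among compartments: ",
           paste(edges$from[bad], "->", edges$to[bad], collapse = ", "))
    if (any(edges$from == edges$to))
      stop("self-edges are not allowed")
    if (anyDuplicated(edges$rate))
      stop("rate parameter names must be unique")
    if (anyDuplicated(paste(edges$from, edges$to)))
      stop("parallel edges between the same compartments are not allowed")
  } else {
    edges <- data.frame(from = character(), to = character(),
                        rate = character(), stringsAsFactors = FALSE)
  }
  for (org in names(observations)) {
    ob <- observations[[org]]
    unknown <- setdiff(ob$compartments, compartments)
    if (length(unknown))
      stop("observation map for '", org, "' references unknown compartments: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(compartments = compartments,
                 edges = edges[c("from", "to", "rate")],
                 observations = observations),
            class = "model_structure")
}

#' @export
print.model_structure <- function(x, ...) {
  cat("<model_structure> ", length(x$compartments), " compartments, ",
      nrow(x$edges), " edges, ", length(x$observations),
      " observed organs\n", sep = "")
  invisible(x)
}

#' Bundle rate constants, blood fractions and the decay constant
#'
#' @param rates Named numeric vector of rate constants \[h^-1\], named by
#'   the structure's edge rate names; all values must be finite and >= 0.
#' @param blood_fractions Named numeric vector of organ blood fractions
#'   (as fractions in \[0, 1\], not percent), named by the blood-fraction
#'   parameter names used in a structure's observation map.
#' @param lambda Physical decay constant \[h^-1\], >= 0.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(rates, blood_fractions = numeric(), lambda = 0) {
  rates <- unlist(rates)
  blood_fractions <- unlist(blood_fractions)
  if (length(rates) && (is.null(names(rates)) || any(names(rates) == "")))
    stop("rates must be named")
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rate constants must be finite and non-negative")
  if (length(blood_fractions) &&
      (any(!is.finite(blood_fractions)) ||
       any(blood_fractions < 0) || any(blood_fractions > 1)))
    stop("blood fractions must lie in [0, 1]")
  if (!is.finite(lambda) || lambda < 0)
    stop("lambda must be finite and non-negative")
  structure(list(rates = rates, blood_fractions = blood_fractions,
                 lambda = lambda),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", length(x$rates), " rates, ",
      length(x$blood_fractions), " blood fractions, lambda = ",
      signif(x$lambda, 5), " h^-1\n", sep = "")
  invisible(x)
}

check_params <- function(structure, params) {
  missing_rates <- setdiff(structure$edges$rate, names(params$rates))
  if (length(missing_rates))
    stop("missing rate value(s) for edge(s): ",
         paste(missing_rates, collapse = ", "))
  bf_needed <- stats::na.omit(vapply(structure$observations,
                                     function(o) as.character(o$blood_fraction %||% NA),
                                     character(1)))
  missing_bf <- setdiff(bf_needed, names(params$blood_fractions))
  if (length(missing_bf))
    stop("missing blood fraction(s): ", paste(missing_bf, collapse = ", "))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# organ definitions shared by the final model and its variants:
# each organ is blood <-> fast -> slow with the slow pool a sink,
# except the tumor (slow -> fast return) and the spleen (single sink).
.clr_organs <- list(
  heart_wall  = list(prefix = "heart",  bf = "f_heart_wall"),
  kidneys     = list(prefix = "kidney", bf = "f_kidneys"),
  tumor       = list(prefix = "tumor",  bf = NA),
  lungs       = list(prefix = "lung",   bf = "f_lungs"),
  liver       = list(prefix = "liver",  bf = "f_liver"),
  bone_marrow = list(prefix = "bm",     bf = "f_bone_marrow")
)

#' The final 17-compartment CLR1404 biokinetic model
#'
#' Assembles the published model structure: blood plus fast/slow tissue
#' pairs for heart wall, kidneys, tumor, lungs, liver, bone marrow and
#' remaining tissues (RT), a single sink compartment for the spleen, and
#' urinary-bladder contents fed from the kidney fast pool. Slow pools are
#' sinks except the tumor's, which returns to its fast pool. The
#' observation map exposes the nine measured series (six organs, tumor,
#' blood, bladder contents); tumor and bladder blood fractions are
#' treated as negligible.
#'
#' @return A [model_structure] with 17 compartments and 24 edges.
#' @examples
#' m <- clr_final_model()
#' length(m$compartments)  # 17
#' nrow(m$edges)           # 24
#' @export
clr_final_model <- function() {
  comp <- c("blood",
            paste0(rep(c("heart", "kidney", "tumor", "lung", "liver",
                         "bm", "rt"), each = 2), c("_fast", "_slow")),
            "spleen", "bladder")
  e <- function(from, to) data.frame(from = from, to = to,
                                     stringsAsFactors = FALSE)
  edges <- do.call(rbind, c(
    lapply(c("heart", "kidney", "tumor", "lung", "liver", "bm", "rt"),
           function(p) rbind(e("blood", paste0(p, "_fast")),
                             e(paste0(p, "_fast"), "blood"),
                             e(paste0(p, "_fast"), paste0(p, "_slow")))),
    list(e("tumor_slow", "tumor_fast"),
         e("kidney_fast", "bladder"),
         e("blood", "spleen"))
  ))
  obs <- lapply(.clr_organs, function(o)
    list(compartments = paste0(o$prefix, c("_fast", "_slow")),
         blood_fraction = o$bf))
  obs$spleen  <- list(compartments = "spleen",  blood_fraction = "f_spleen")
  obs$bladder <- list(compartments = "bladder", blood_fraction = NA)
  obs$blood   <- list(compartments = "blood",   blood_fraction = NA)
  model_structure(comp, edges, obs)
}

#' Published best-fit parameters of the final model
#'
#' Rate constants \[h^-1\] and blood fractions of the final
#' 17-compartment model as printed (to about two significant figures) in
#' the source study, with the physical decay constant of the requested
#' nuclide.
#'
#' @param nuclide Passed to [decay_constant()]; default `"I131"`.
#' @return A [parameter_set] with 24 rates and 6 blood fractions.
#' @export
clr_reference_parameters <- function(nuclide = "I131") {
  rates <- c(
    k_blood_heart_fast  = 2.3e-1,
    k_heart_fast_blood  = 6.8,
    k_heart_fast_heart_slow = 9.3e-4,
    k_blood_kidney_fast = 1.2e-2,
    k_kidney_fast_blood = 4.1e-1,
    k_kidney_fast_kidney_slow = 2.1e-3,
    k_blood_tumor_fast  = 1.7e-2,
    k_tumor_fast_blood  = 2.0e1,
    k_tumor_fast_tumor_slow = 1.0e-1,
    k_tumor_slow_tumor_fast = 2.6e-2,
    k_blood_lung_fast   = 3.4e-3,
    k_lung_fast_blood   = 5.0e-2,
    k_lung_fast_lung_slow = 3.6e-3,
    k_blood_liver_fast  = 6.1e-2,
    k_liver_fast_blood  = 9.2e-1,
    k_liver_fast_liver_slow = 2.5e-3,
    k_blood_bm_fast     = 1.0e-3,
    k_bm_fast_blood     = 2.9e-2,
    k_bm_fast_bm_slow   = 2.0e-3,
    k_blood_rt_fast     = 3.6e-2,
    k_rt_fast_blood     = 2.8e-2,
    k_rt_fast_rt_slow   = 1.1e-3,
    k_kidney_fast_bladder = 1.9e-2,
    k_blood_spleen      = 1.6e-5
  )
  bf <- c(f_bone_marrow = 3.9, f_heart_wall = 0.8, f_kidneys = 2.7,
          f_liver = 8.2, f_lungs = 7.7, f_spleen = 1.3) / 100
  parameter_set(rates, bf, decay_constant(nuclide))
}

#' Reference organ masses and blood fractions
#'
#' Returns the reference tables shipped with the package: adult female
#' ICRP organ masses \[g\] with initial blood fractions \[%\] used for the
#' clinical data, or the 30 g murine phantom masses used for the
#' xenograft data.
#'
#' @param which `"human"` or `"murine"`.
#' @return Data frame with columns `organ`, `mass_g`,
#'   `blood_fraction_pct`.
#' @export
reference_masses <- function(which = c("human", "murine")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_reference.csv"),
                      package = "clrkinetics", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference blood fractions as parameters
#'
#' Convenience accessor turning the human reference table into a named
#' vector of blood fractions (as fractions) keyed by the blood-fraction
#' parameter names of [clr_final_model()].
#'
#' @return Named numeric vector.
#' @export
clr_reference_blood_fractions <- function() {
  tab <- reference_masses("human")
  key <- c(heart_wall = "f_heart_wall", kidneys = "f_kidneys",
           liver = "f_liver", lungs = "f_lungs",
           bone_marrow = "f_bone_marrow", spleen = "f_spleen")
  out <- stats::setNames(tab$blood_fraction_pct[match(names(key), tab$organ)] / 100,
                         unname(key))
  out[!is.na(out)]
}
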