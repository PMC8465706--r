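#' Default acquisition schedules
#'
#' `clinical_schedule()` emulates the structure of the clinical data
#' the model was built on: PET-like organ sampling up to 120 h and
#' SPECT-like sampling from 120 to 505 h post-injection, with 5%
#' relative noise everywhere except the SPECT-derived tumor points
#' (10%, reflecting the PET/SPECT calibration mismatch), plus blood and
#' urine (bladder-content) series. `xenograft_schedule()` emulates the
#' murine PET study: organ and tumor series only, no blood or
#' excretion data.
#'
#' @param pet_times,spect_times,blood_times,urine_times Sampling times
#'   \[h\].
#' @return Data frame with columns `organ`, `time_h`, `modality`,
#'   `rel_sd`.
#' @export
clinical_schedule <- function(pet_times = c(2, 5, 24, 48, 72, 120),
                              spect_times = c(170, 330, 505),
                              blood_times = c(0.25, 0.5, 1, 2, 5, 24, 48,
                                              72, 120),
                              urine_times = c(2, 5, 24, 48, 72, 120, 170,
                                              330, 505)) {
  organs <- c("heart_wall", "kidneys", "tumor", "lungs", "liver",
              "bone_marrow", "spleen")
  org <- do.call(rbind, lapply(organs, function(o)
    data.frame(organ = o,
               time_h = c(pet_times, spect_times),
               modality = rep(c("PET", "SPECT"),
                              c(length(pet_times), length(spect_times))),
               stringsAsFactors = FALSE)))
  org$rel_sd <- ifelse(org$organ == "tumor" & org$modality == "SPECT",
                       0.10, 0.05)
  extra <- rbind(
    data.frame(organ = "blood", time_h = blood_times, modality = "blood",
               rel_sd = 0.05, stringsAsFactors = FALSE),
    data.frame(organ = "bladder", time_h = urine_times, modality = "urine",
               rel_sd = 0.05, stringsAsFactors = FALSE))
  rbind(org, extra)
}

#' @rdname clinical_schedule
#' @param times Sampling times for the murine series.
#' @export
xenograft_schedule <- function(times = c(1, 4, 24, 48, 72, 120)) {
  organs <- c("heart_wall", "kidneys", "liver", "lungs", "bone_marrow",
              "tumor")
  do.call(rbind, lapply(organs, function(o)
    data.frame(organ = o, time_h = times, modality = "PET", rel_sd = 0.05,
               stringsAsFactors = FALSE)))
}

noise_factor <- function(n, rel_sd, noise) {
  switch(noise,
         none = rep(1, n),
         truncnorm = pmax(1 + rel_sd * stats::rnorm(n), 0),
         lognormal = {
           sdlog <- sqrt(log(1 + rel_sd^2))
           stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
         },
         stop("unknown noise model: ", noise))
}

#' Generate a synthetic time-activity dataset
#'
#' Solves the model from a 100% bolus in blood, evaluates every organ
#' observable at the scheduled times, applies multiplicative relative
#' noise (truncated-normal by default, the scheduled `rel_sd` per
#' point), and attaches matching sigmas. The result has exactly the
#' statistical structure the fitting pipeline assumes, so every stage
#' is testable without external data.
#'
#' @param structure A [model_structure]; the schedule may only
#'   reference its observed organs.
#' @param params A [parameter_set]: the ground truth.
#' @param schedule A schedule data frame, e.g. [clinical_schedule()].
#' @param seed Integer seed; datasets are bit-identical given it.
#' @param noise `"truncnorm"` (default), `"lognormal"` or `"none"`.
#' @return A [biokin_dataset] (decay-included percent activities) with
#'   the human reference masses and blood fractions attached.
#' @export
generate_dataset <- function(structure, params,
                             schedule = clinical_schedule(), seed = 1L,
                             noise = c("truncnorm", "lognormal", "none")) {
  noise <- match.arg(noise)
  unknown <- setdiff(unique(schedule$organ), names(structure$observations))
  if (length(unknown))
    stop("schedule references unknown organ(s): ",
         paste(unknown, collapse = ", "))
  times <- sort(unique(schedule$time_h))
  traj <- solve_activities(structure, params, times)
  set.seed(seed)
  p <- schedule
  p$value <- NA_real_
  for (org in unique(p$organ)) {
    a <- organ_activity(traj, structure, params, org)
    rows <- p$organ == org
    p$value[rows] <- a[match(p$time_h[rows], traj$times)]
  }
  p$value <- p$value * noise_factor(nrow(p), p$rel_sd, noise)
  p$sigma <- p$rel_sd * abs(p$value)
  p$units <- "percent"
  p$decay <- "decay_included"
  ref <- reference_masses("human")
  biokin_dataset(p[c("organ", "time_h", "value", "sigma", "modality",
                     "units", "decay")],
                 masses = stats::setNames(ref$mass_g, ref$organ),
                 ref_blood_fractions = stats::setNames(
                   ref$blood_fraction_pct, ref$organ))
}

#' Generate synthetic xenograft datasets
#'
#' One dataset per tumor line: all lines share the organ kinetics, each
#' line overrides the tumor parameters. Organ activities are expressed
#' as concentrations \[%/g\] using the murine phantom masses (so the
#' mass-scaling step of the data processing is exercised); the tumor
#' series stays in percent (its mass is line-specific and not part of
#' the phantom table). No blood or excretion series are produced,
#' mirroring the murine study.
#'
#' @param params Shared [parameter_set] (ground truth for the organs).
#' @param tumor_overrides Named list, one entry per tumor line, each a
#'   named numeric vector of rate values replacing the shared ones
#'   (e.g. `k_blood_tumor_fast`).
#' @param structure A [model_structure]; default [clr_final_model()].
#' @param schedule Default [xenograft_schedule()].
#' @param seed,noise As in [generate_dataset()].
#' @return Named list of [biokin_dataset]s, one per tumor line, with
#'   murine masses attached.
#' @export
generate_xenograft_dataset <- function(params, tumor_overrides,
                                       structure = clr_final_model(),
                                       schedule = xenograft_schedule(),
                                       seed = 1L,
                                       noise = c("truncnorm", "lognormal",
                                                 "none")) {
  noise <- match.arg(noise)
  if (!length(tumor_overrides) || length(tumor_overrides) > 4)
    stop("1 to 4 tumor lines expected")
  ref <- reference_masses("murine")
  masses <- stats::setNames(ref$mass_g, ref$organ)
  out <- list()
  for (j in seq_along(tumor_overrides)) {
    pj <- params
    ov <- tumor_overrides[[j]]
    unknown <- setdiff(names(ov), names(pj$rates))
    if (length(unknown))
      stop("unknown tumor rate(s): ", paste(unknown, collapse = ", "))
    pj$rates[names(ov)] <- ov
    ds <- generate_dataset(structure, pj, schedule, seed = seed + j,
                           noise = noise)
    p <- ds$points
    conv <- p$organ %in% names(masses)
    m <- masses[p$organ[conv]]
    p$value[conv] <- p$value[conv] / m
    p$sigma[conv] <- p$sigma[conv] / m
    p$units[conv] <- "percent_per_gram"
    out[[names(tumor_overrides)[j] %||% paste0("line", j)]] <-
      biokin_dataset(p, masses = masses,
                     ref_blood_fractions = stats::setNames(
                       ref$blood_fraction_pct, ref$organ))
  }
  out
}
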