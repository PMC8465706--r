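organ_prefixes <- c(heart_wall = "heart", kidneys = "kidney",
                    tumor = "tumor", lungs = "lung", liver = "liver",
                    bone_marrow = "bm", rt = "rt")

#' Assemble a full model from per-organ winning variants
#'
#' Translates the decoupling winners (one variant tag per organ plus an
#' excretion scheme) into a single full-model structure with
#' organ-prefixed compartment and rate names. With the published
#' winning tags this reproduces [clr_final_model()] exactly.
#'
#' @param organ_tags Named character vector of variant tags (see
#'   [enumerate_variants()]) over the organs; `rt` (remaining tissues)
#'   defaults to `2c_slow_sink` and `spleen` to `1c_sink` when absent.
#' @param excretion_tag Excretion scheme tag; default
#'   `"kidney_path_minimal"`.
#' @return A [model_structure].
#' @export
assemble_model <- function(organ_tags, excretion_tag = "kidney_path_minimal") {
  if (!"rt" %in% names(organ_tags)) organ_tags["rt"] <- "2c_slow_sink"
  if (!"spleen" %in% names(organ_tags)) organ_tags["spleen"] <- "1c_sink"
  comps <- "blood"
  edges <- NULL
  obs <- list()
  e <- function(from, to) data.frame(from = from, to = to,
                                     stringsAsFactors = FALSE)
  for (org in names(organ_tags)) {
    pf <- if (org == "spleen") "spleen" else organ_prefixes[[org]]
    tag <- organ_tags[[org]]
    bf <- if (org == "tumor") NA else if (org == "rt") NA
          else paste0("f_", org)
    if (tag %in% c("1c_bidirectional", "1c_sink")) {
      comps <- c(comps, pf)
      edges <- rbind(edges, e("blood", pf),
                     if (tag == "1c_bidirectional") e(pf, "blood"))
      members <- pf
    } else if (tag %in% c("2c_4rates", "2c_slow_sink")) {
      fast <- paste0(pf, "_fast"); slow <- paste0(pf, "_slow")
      comps <- c(comps, fast, slow)
      edges <- rbind(edges, e("blood", fast), e(fast, "blood"),
                     e(fast, slow),
                     if (tag == "2c_4rates") e(slow, fast))
      members <- c(fast, slow)
    } else stop("unknown organ variant tag: ", tag)
    if (org != "rt")
      obs[[org]] <- list(compartments = members, blood_fraction = bf)
  }
  comps <- c(comps, "bladder")
  obs$bladder <- list(compartments = "bladder", blood_fraction = NA)
  obs$blood <- list(compartments = "blood", blood_fraction = NA)
  kidney_fast <- if ("kidney_fast" %in% comps) "kidney_fast" else "kidney"
  if (grepl("^kidney_path", excretion_tag)) {
    edges <- rbind(edges, e(kidney_fast, "bladder"))
    if (excretion_tag %in% c("kidney_path_full", "kidney_path_no_slow_fast"))
      edges <- rbind(edges, e("blood", "bladder"))
    if (excretion_tag %in% c("kidney_path_full", "kidney_path_no_blood_bladder")
        && "kidney_slow" %in% comps)
      edges <- rbind(edges, e("kidney_slow", "kidney_fast"))
  } else if (grepl("^urinary_path", excretion_tag)) {
    comps <- c(comps, "upath")
    edges <- rbind(edges, e("blood", "upath"), e("upath", "bladder"),
                   if (excretion_tag == "urinary_path_with_return")
                     e("upath", "blood"))
  } else stop("unknown excretion tag: ", excretion_tag)
  model_structure(comps, edges, obs)
}

# map a subsystem fit's generic parameter names (tissue/fast/slow) onto
# the assembled model's organ-prefixed names
rename_subsystem_params <- function(fit, org) {
  pf <- if (org == "spleen") "spleen" else organ_prefixes[[org]]
  single <- pf
  map <- c(k_blood_tissue = rate_name("blood", single),
           k_tissue_blood = rate_name(single, "blood"),
           k_blood_fast = rate_name("blood", paste0(pf, "_fast")),
           k_fast_blood = rate_name(paste0(pf, "_fast"), "blood"),
           k_fast_slow = rate_name(paste0(pf, "_fast"), paste0(pf, "_slow")),
           k_slow_fast = rate_name(paste0(pf, "_slow"), paste0(pf, "_fast")))
  r <- fit$params$rates
  names(r) <- ifelse(names(r) %in% names(map), map[names(r)], names(r))
  r
}

#' Run the full model-construction pipeline on synthetic data
#'
#' Executes the whole workflow end to end at a configurable (by
#' default modest) computational scale: generate a synthetic clinical
#' dataset from a ground truth; fit the blood forcing function;
#' decouple and rank the candidate subsystems per organ and for
#' excretion; assemble the winning structure; fit the complete model
#' (decoupling results seed the initial values); Sobol-screen the
#' fitted parameters and prune/refit if indicated; estimate parameter
#' uncertainty by Monte Carlo refits; and tabulate cumulated-activity
#' comparisons against the simplified estimators. Each stage writes
#' its CSV/JSON artifact into `out_dir`, stamped with the seed and a
#' config fingerprint.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for every stochastic stage.
#' @param truth Ground-truth [parameter_set]; default
#'   [clr_reference_parameters()].
#' @param structure Generating [model_structure]; default
#'   [clr_final_model()].
#' @param noise Noise model for the synthetic data.
#' @param sa_control Annealer control shared by the fitting stages.
#' @param sobol_M Samples per Sobol block.
#' @param mc_runs Monte Carlo uncertainty runs.
#' @param organs Organs to decouple; default all with data.
#' @return Invisible list with every stage's in-memory result.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         truth = clr_reference_parameters(),
                         structure = clr_final_model(),
                         noise = "truncnorm",
                         sa_control = list(n_temps = 20L, steps = 20L),
                         sobol_M = 128L, mc_runs = 4L,
                         organs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(seed = seed, noise = noise, sa_control = sa_control,
              sobol_M = sobol_M, mc_runs = mc_runs)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  stamp <- list(seed = seed, config_hash = config_fingerprint(as.character(cfg_json)))
  jsonlite::write_json(c(cfg, stamp["config_hash"]),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                                "\n", sep = "", file = logf, append = TRUE)
  cat("# pipeline log; seed=", seed, " config=", stamp$config_hash, "\n",
      sep = "", file = logf)

  log_line("stage synth")
  ds <- generate_dataset(structure, truth, seed = seed, noise = noise)
  write_tac_csv(ds, file.path(out_dir, "dataset.csv"))

  log_line("stage decouple")
  ff <- fit_forcing_function(ds)
  jsonlite::write_json(c(unclass(ff), wrss = attr(ff, "wrss"), stamp),
                       file.path(out_dir, "forcing.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  refbf <- clr_reference_blood_fractions()
  if (is.null(organs))
    organs <- intersect(names(structure$observations),
                        c(names(organ_prefixes), "spleen"))
  # the kidney-path excretion schemes need the kidney subsystem
  organs <- union(organs, "kidneys")
  winners <- character()
  init_rates <- c()
  init_bfs <- c()
  for (org in organs) {
    bfn <- structure$observations[[org]]$blood_fraction
    vs <- enumerate_variants(org, blood_fraction_name = bfn %||% NA)
    fits <- lapply(vs, function(v)
      fit_subsystem(ff, ds, v, organ = org,
                    ref_blood_fraction = if (!is.na(bfn)) refbf[[bfn]],
                    seed = seed, control = sa_control))
    sel <- select_structure(fits)
    utils::write.csv(sel$ranking,
                     file.path(out_dir, paste0("decouple_", org, ".csv")),
                     row.names = FALSE)
    winners[org] <- sel$winner$tag
    init_rates <- c(init_rates, rename_subsystem_params(sel$winner, org))
    init_bfs <- c(init_bfs, sel$winner$params$blood_fractions)
    log_line("  ", org, " -> ", sel$winner$tag)
  }
  exc_fits <- lapply(enumerate_variants("bladder", excretion = TRUE),
                     function(v) fit_subsystem(ff, ds, v,
                                               ref_blood_fraction =
                                                 refbf["f_kidneys"],
                                               seed = seed,
                                               control = sa_control))
  exc_sel <- select_structure(exc_fits)
  utils::write.csv(exc_sel$ranking,
                   file.path(out_dir, "decouple_excretion.csv"),
                   row.names = FALSE)
  log_line("  excretion -> ", exc_sel$winner$tag)

  log_line("stage assemble")
  assembled <- assemble_model(winners, exc_sel$winner$tag)
  exc_rates <- exc_sel$winner$params$rates
  keep <- names(exc_rates) %in% assembled$edges$rate
  init_rates <- c(init_rates, exc_rates[keep])
  write_structure_json(assembled, file.path(out_dir, "structure.json"))

  log_line("stage fit")
  start <- stats::setNames(rep(1e-3, nrow(assembled$edges)),
                           assembled$edges$rate)
  start[intersect(names(init_rates), names(start))] <-
    init_rates[intersect(names(init_rates), names(start))]
  init <- parameter_set(pmin(pmax(start, 1e-8), 1e2),
                        refbf, truth$lambda)
  fit <- fit_full_model(ds, assembled, lambda = truth$lambda, init = init,
                        seed = seed, control = sa_control)
  write_fit_json(fit, file.path(out_dir, "fit.json"))
  log_line("  WRSS = ", signif(fit$wrss, 6), ", AICc = ",
           signif(fit$aicc, 6))

  log_line("stage sobol")
  ev <- make_wrss_evaluator(ds, assembled, truth$lambda)
  nr <- length(ev$rate_names)
  base <- c(fit$params$rates[ev$rate_names],
            fit$params$blood_fractions[ev$bf_names])
  des <- sobol_design(base, M = sobol_M, rel_sd = 0.10, seed = seed)
  sres <- sobol_indices(function(x)
    ev$fn(x[seq_len(nr)], x[-seq_len(nr)]), des)
  utils::write.csv(sres$indices, file.path(out_dir, "sobol.csv"),
                   row.names = FALSE)
  prunable <- intersect(prune_parameters(sres), ev$rate_names)
  final_structure <- assembled
  final_fit <- fit
  if (length(prunable)) {
    log_line("  pruning: ", paste(prunable, collapse = ", "))
    keep_edges <- !(assembled$edges$rate %in% prunable)
    final_structure <- model_structure(assembled$compartments,
                                       assembled$edges[keep_edges, ],
                                       assembled$observations)
    final_fit <- fit_full_model(ds, final_structure, lambda = truth$lambda,
                                init = fit$params, seed = seed,
                                control = sa_control)
    write_fit_json(final_fit, file.path(out_dir, "fit_pruned.json"))
  }

  log_line("stage uncertainty")
  unc <- mc_uncertainty(ds, final_structure, lambda = truth$lambda,
                        runs = mc_runs, seed = seed,
                        fit_args = list(init = final_fit$params,
                                        control = list(n_temps = 5L,
                                                       steps = 10L)))
  utils::write.csv(unc$summary, file.path(out_dir, "uncertainty.csv"),
                   row.names = FALSE)

  log_line("stage cumact")
  table5_organs <- intersect(c("heart_wall", "kidneys", "tumor", "lungs",
                               "liver", "bone_marrow", "spleen", "bladder"),
                             names(final_structure$observations))
  ref_ct <- cumulated_activity(final_structure, final_fit$params,
                               table5_organs)
  sm_structure <- simplify_structure(final_structure)
  sm_fit <- fit_full_model(ds, sm_structure, lambda = truth$lambda,
                           init = final_fit$params, seed = seed,
                           control = sa_control)
  simpl <- list(SM = cumulated_activity(sm_structure, sm_fit$params,
                                        table5_organs))
  be1 <- be2 <- e24 <- e48 <- e120 <- stats::setNames(
    rep(NA_real_, length(table5_organs)), table5_organs)
  for (org in table5_organs) {
    s <- ds$points[ds$points$organ == org, ]
    b1 <- try(biexp_cumact(s), silent = TRUE)
    if (!inherits(b1, "try-error")) be1[org] <- b1$A_tilde
    b2 <- try(biexp_cumact(s, times = c(2, 24, 120, 505)), silent = TRUE)
    if (!inherits(b2, "try-error")) be2[org] <- b2$A_tilde
    for (tt in c(24, 48, 120)) {
      row <- which(abs(s$time_h - tt) < 1e-9)[1]
      if (!is.na(row)) {
        val <- monoexp_cumact(tt, s$value[row], truth$lambda)
        if (tt == 24) e24[org] <- val
        if (tt == 48) e48[org] <- val
        if (tt == 120) e120[org] <- val
      }
    }
  }
  simpl <- c(simpl, list(BE1 = be1, BE2 = be2, `E_24h` = e24,
                         `E_48h` = e48, `E_120h` = e120))
  comp_tab <- compare_cumulated(ref_ct, simpl)
  utils::write.csv(comp_tab, file.path(out_dir, "cumact_comparison.csv"),
                   row.names = FALSE)
  log_line("done")
  invisible(list(dataset = ds, forcing = ff, winners = winners,
                 excretion = exc_sel$winner$tag, structure = final_structure,
                 fit = final_fit, sobol = sres, uncertainty = unc,
                 comparison = comp_tab, stamp = stamp))
}
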