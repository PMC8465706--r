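test_that("zero-noise generation reproduces the model exactly", {
  m <- clr_final_model()
  p <- clr_reference_parameters()
  ds <- generate_dataset(m, p, seed = 1, noise = "none")
  pred <- predict_dataset(ds, m, p)
  expect_equal(pred$value, pred$predicted, tolerance = 1e-10)
})

test_that("the clinical template has the study's sampling structure", {
  sch <- clinical_schedule()
  expect_setequal(unique(sch$organ),
                  c("heart_wall", "kidneys", "tumor", "lungs", "liver",
                    "bone_marrow", "spleen", "blood", "bladder"))
  # PET-like sampling up to 120 h, SPECT-like in (120, 505]
  expect_true(all(sch$time_h[sch$modality == "PET"] <= 120))
  expect_true(all(sch$time_h[sch$modality == "SPECT"] > 120 &
                    sch$time_h[sch$modality == "SPECT"] <= 505))
  # tumor SPECT carries 10%, everything else 5%
  expect_true(all(sch$rel_sd[sch$organ == "tumor" &
                               sch$modality == "SPECT"] == 0.10))
  expect_true(all(sch$rel_sd[!(sch$organ == "tumor" &
                                 sch$modality == "SPECT")] == 0.05))
  ds <- generate_dataset(clr_final_model(), clr_reference_parameters(),
                         seed = 1)
  expect_length(unique(ds$points$organ), 9)
  expect_equal(ds$points$sigma, ds$points$value *
                 ifelse(ds$points$organ == "tumor" &
                          ds$points$modality == "SPECT", 0.10, 0.05))
})

test_that("generation is seed-deterministic and validates organs", {
  m <- clr_final_model(); p <- clr_reference_parameters()
  d1 <- generate_dataset(m, p, seed = 9)
  d2 <- generate_dataset(m, p, seed = 9)
  expect_identical(d1$points, d2$points)
  d3 <- generate_dataset(m, p, seed = 10)
  expect_false(identical(d1$points$value, d3$points$value))
  bad <- data.frame(organ = "brain", time_h = 1, modality = "PET",
                    rel_sd = 0.05)
  expect_error(generate_dataset(m, p, schedule = bad), "unknown organ")
})

test_that("replicate scatter matches the nominal relative SD", {
  sm <- small_organ_model()
  sched <- data.frame(organ = "organ", time_h = 24,
                      modality = "synthetic", rel_sd = 0.05)
  vals <- vapply(seq_len(1000), function(seed)
    generate_dataset(sm$structure, sm$params, sched, seed = seed)$points$value,
    numeric(1))
  cv <- stats::sd(vals) / mean(vals)
  expect_lt(abs(cv - 0.05) / 0.05, 0.05)
  # lognormal noise keeps the same coefficient of variation
  vl <- vapply(seq_len(1000), function(seed)
    generate_dataset(sm$structure, sm$params, sched, seed = seed,
                     noise = "lognormal")$points$value, numeric(1))
  expect_lt(abs(stats::sd(vl) / mean(vl) - 0.05) / 0.05, 0.05)
})

test_that("xenograft data are concentrations that round-trip to percent", {
  p <- clr_reference_parameters()
  lines <- list(line_a = c(k_blood_tumor_fast = 0.02),
                line_b = c(k_blood_tumor_fast = 0.005))
  xs <- generate_xenograft_dataset(p, lines, seed = 4, noise = "none")
  expect_length(xs, 2)
  expect_named(xs, c("line_a", "line_b"))
  ds <- xs$line_a
  # no blood or excretion series in the murine template
  expect_false(any(c("blood", "bladder", "spleen") %in% ds$points$organ))
  # organs are in %/g, the tumor stays in percent
  hw <- ds$points[ds$points$organ == "heart_wall", ]
  expect_true(all(hw$units == "percent_per_gram"))
  expect_true(all(ds$points$units[ds$points$organ == "tumor"] == "percent"))
  # heart mass 0.291 g converts back to the model prediction (computed
  # with the line's own tumor parameters)
  p_a <- p; p_a$rates[names(lines$line_a)] <- lines$line_a
  abs_ds <- concentration_to_activity(ds)
  pred <- predict_dataset(abs_ds, clr_final_model(), p_a)
  expect_equal(pred$value, pred$predicted, tolerance = 1e-10)
  # tumor kinetics differ between lines (and propagate through blood)
  expect_false(isTRUE(all.equal(
    xs$line_a$points$value[xs$line_a$points$organ == "tumor"],
    xs$line_b$points$value[xs$line_b$points$organ == "tumor"])))
  single <- generate_xenograft_dataset(p, lines[1], seed = 4)
  expect_length(single, 1)
  expect_error(generate_xenograft_dataset(p, list(), seed = 1),
               "tumor lines")
  expect_error(generate_xenograft_dataset(
    p, list(a = c(k_nonexistent = 1)), seed = 1), "unknown tumor rate")
})

test_that("tied xenograft truths are recoverable by the joint fit", {
  p <- clr_reference_parameters()
  st <- clr_final_model()
  lines <- list(a = c(k_blood_tumor_fast = 0.03),
                b = c(k_blood_tumor_fast = 0.008))
  xs <- generate_xenograft_dataset(p, lines, seed = 6, noise = "none")
  dss <- lapply(xs, concentration_to_activity)
  tumor_free <- grep("tumor", names(p$rates), value = TRUE)
  jf <- suppressWarnings(fit_joint(
    dss, st, free = tumor_free, lambda = p$lambda, init = p,
    ref_blood_fractions = p$blood_fractions,
    seed = 8, control = list(n_temps = 6, steps = 8)))
  expect_equal(jf$subject_params[[1]]$rates[["k_blood_tumor_fast"]], 0.03,
               tolerance = 0.05)
  expect_equal(jf$subject_params[[2]]$rates[["k_blood_tumor_fast"]], 0.008,
               tolerance = 0.05)
})
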