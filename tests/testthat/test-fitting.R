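test_that("WRSS arithmetic, scaling and ordering invariance", {
  expect_equal(wrss(c(10, 5), c(10, 5), c(1, 1)), 0)
  expect_equal(wrss(c(10, 5), c(9, 6), c(1, 1)), 2)
  expect_equal(wrss(c(10, 5), c(9, 6), c(2, 2)), 0.5)
  # re-ordering points leaves the objective unchanged
  o <- c(3, 1, 4); p <- c(2, 1, 5); s <- c(0.5, 1, 2)
  expect_equal(wrss(o, p, s), wrss(rev(o), rev(p), rev(s)))
  expect_error(wrss(1, 1, 0), "positive")
  expect_error(wrss(1:2, 1:3, 1:2), "aligned")
})

test_that("forcing function recovers noise-free biexponentials", {
  t <- c(0.25, 0.5, 1, 2, 5, 12, 24, 48, 96, 120)
  truth <- forcing_function(60, 40, 0.5, 0.01)
  s <- data.frame(time_h = t, value = eval_forcing(truth, t))
  ff <- fit_forcing_function(s)
  expect_equal(ff$A1, 60, tolerance = 1e-6)
  expect_equal(ff$A2, 40, tolerance = 1e-6)
  expect_equal(ff$alpha1, 0.5, tolerance = 1e-6)
  expect_equal(ff$alpha2, 0.01, tolerance = 1e-6)
  expect_equal(ff$A1 + ff$A2, 100, tolerance = 1e-9)  # amplitude constraint
  expect_error(fit_forcing_function(s[1:3, ]), "4 blood points")
})

test_that("forcing-function rates are recovered within sampling error", {
  t <- c(0.25, 0.5, 1, 2, 5, 12, 24, 48, 96, 120)
  truth <- forcing_function(60, 40, 0.5, 0.01)
  base <- eval_forcing(truth, t)
  set.seed(42)
  a1 <- a2 <- numeric(60)
  for (i in 1:60) {
    v <- base * (1 + 0.05 * rnorm(length(t)))
    ff <- fit_forcing_function(data.frame(time_h = t, value = v,
                                          sigma = 0.05 * base))
    a1[i] <- ff$alpha1; a2[i] <- ff$alpha2
  }
  # median recovered rates sit within ~3 relative SDs of truth
  expect_lt(abs(stats::median(a1) - 0.5) / (3 * stats::sd(a1)), 1)
  expect_lt(abs(stats::median(a2) - 0.01) / (3 * stats::sd(a2)), 1)
})

test_that("simulated annealing finds a convex minimum deterministically", {
  target <- c(0.2, 1.5, 0.03)
  fn <- function(x) sum((log(x) - log(target))^2)
  res <- simulated_annealing(fn, c(1, 1, 1), 1e-6, 1e3, seed = 4,
                             control = list(n_temps = 80, steps = 60))
  expect_lt(res$value, 1e-3)
  # fixed seed is bit-reproducible
  res2 <- simulated_annealing(fn, c(1, 1, 1), 1e-6, 1e3, seed = 4,
                              control = list(n_temps = 80, steps = 60))
  expect_identical(res$par, res2$par)
  # best-so-far record never increases
  expect_true(all(diff(res$trace) <= 0))
  # zero temperature levels returns the start point
  res0 <- simulated_annealing(fn, c(1, 1, 1), 1e-6, 1e3, seed = 4,
                              control = list(n_temps = 0, steps = 0))
  expect_identical(res0$par, c(1, 1, 1))
  expect_error(simulated_annealing(fn, c(2e3, 1, 1), 1e-6, 1e3, seed = 1),
               "bounds")
})

test_that("nested subsystem variants agree on data from the simpler truth", {
  # data generated from a pure sink (no tissue-to-blood return)
  ff <- forcing_function(60, 40, 0.3, 0.008)
  t <- c(2, 5, 24, 48, 72, 120, 170, 330, 505)
  vs <- enumerate_variants("organ", blood_fraction_name = "f_organ")
  sink_v <- vs[[2]]; bidir_v <- vs[[1]]
  truth <- c(k_blood_tissue = 0.02)
  sys <- clrkinetics:::forced_system(sink_v$structure, ff, truth,
                                     decay_constant("I131"), "organ", 0.05)
  pred <- as.numeric(clrkinetics:::expm_action(sys$A, sys$y0, t) %*% sys$w)
  s <- data.frame(organ = "organ", time_h = t, value = pred,
                  sigma = 0.05 * pred)
  f_sink <- fit_subsystem(ff, s, sink_v, organ = "organ",
                          ref_blood_fraction = 0.05, seed = 1,
                          control = list(n_temps = 15, steps = 15))
  f_bid <- fit_subsystem(ff, s, bidir_v, organ = "organ",
                         ref_blood_fraction = 0.05, seed = 1,
                         control = list(n_temps = 15, steps = 15))
  expect_lt(f_sink$wrss, 1e-8)
  expect_lt(f_bid$wrss, 1e-6)
  # the superfluous return rate collapses to the lower bound
  expect_lt(f_bid$params$rates[["k_tissue_blood"]], 1e-6)
  expect_equal(f_sink$params$rates[["k_blood_tissue"]], 0.02,
               tolerance = 1e-4)
})

test_that("all-zero organ data drives rates to zero", {
  ff <- forcing_function(60, 40, 0.3, 0.008)
  s <- data.frame(organ = "organ", time_h = c(2, 24, 120, 505),
                  value = 0, sigma = 1)
  v <- enumerate_variants("organ")[[2]]
  f <- fit_subsystem(ff, s, v, organ = "organ", seed = 1,
                     control = list(n_temps = 10, steps = 10))
  expect_lt(f$params$rates[["k_blood_tissue"]], 1e-6)
  expect_lt(f$wrss, 1e-8)
})

test_that("full-model fitting recovers a small noise-free truth", {
  sm <- small_organ_model()
  ds <- generate_dataset(sm$structure, sm$params,
                         schedule = data.frame(
                           organ = rep(c("organ", "blood"), each = 8),
                           time_h = rep(c(1, 2, 5, 24, 72, 120, 330, 505), 2),
                           modality = "synthetic", rel_sd = 0.05),
                         seed = 1, noise = "none")
  init <- sm$params; init$rates <- init$rates * 3
  fit <- fit_full_model(ds, sm$structure, lambda = sm$params$lambda,
                        init = init,
                        ref_blood_fractions = sm$params$blood_fractions,
                        seed = 2, control = list(n_temps = 15, steps = 15))
  expect_lt(fit$wrss, 1e-8)
  expect_equal(fit$params$rates[names(sm$params$rates)], sm$params$rates,
               tolerance = 1e-4)
  expect_equal(fit$K, 4)  # 3 rates + 1 blood fraction
  expect_equal(fit$N, 16)
  expect_equal(fit$gof, fit$wrss / (fit$N - fit$K))
})

test_that("blood-fraction window is +/-30% of the reference", {
  b <- clrkinetics:::bf_bounds("f_kidneys", c(f_kidneys = 0.02), 0.30)
  expect_equal(unname(b$lower), 0.014)
  expect_equal(unname(b$upper), 0.026)
})

test_that("organs without data are excluded with a warning", {
  sm <- small_organ_model()
  ds <- generate_dataset(sm$structure, sm$params,
                         schedule = data.frame(organ = "blood",
                                               time_h = c(1, 2, 5, 24),
                                               modality = "blood",
                                               rel_sd = 0.05),
                         seed = 1, noise = "none")
  expect_warning(
    fit_full_model(ds, sm$structure, lambda = sm$params$lambda,
                   ref_blood_fractions = sm$params$blood_fractions,
                   seed = 1, control = list(n_temps = 2, steps = 2),
                   polish = FALSE),
    "organ")
})

test_that("joint fitting recovers shared and per-subject parameters", {
  sm <- small_organ_model()
  sched <- data.frame(organ = rep(c("organ", "blood"), each = 6),
                      time_h = rep(c(1, 5, 24, 72, 170, 505), 2),
                      modality = "synthetic", rel_sd = 0.05)
  truth2 <- sm$params
  truth2$rates[["k_blood_fast"]] <- 0.12  # subject-specific uptake
  ds1 <- generate_dataset(sm$structure, sm$params, sched, seed = 1,
                          noise = "none")
  ds2 <- generate_dataset(sm$structure, truth2, sched, seed = 2,
                          noise = "none")
  jf <- fit_joint(list(ds1, ds2), sm$structure, free = "k_blood_fast",
                  lambda = sm$params$lambda,
                  init = sm$params,
                  ref_blood_fractions = sm$params$blood_fractions,
                  seed = 3, control = list(n_temps = 10, steps = 15))
  expect_lt(jf$wrss, 1e-6)
  expect_equal(jf$subject_params[[1]]$rates[["k_blood_fast"]], 0.05,
               tolerance = 1e-3)
  expect_equal(jf$subject_params[[2]]$rates[["k_blood_fast"]], 0.12,
               tolerance = 1e-3)
  expect_equal(jf$K, 3 + 1 + 1)  # shared (2 rates + bf) + one free per subject

  # a single subject reduces to the full-model fit
  f1 <- fit_joint(list(ds1), sm$structure, free = character(),
                  lambda = sm$params$lambda, init = sm$params,
                  ref_blood_fractions = sm$params$blood_fractions,
                  seed = 4, control = list(n_temps = 5, steps = 5))
  f2 <- fit_full_model(ds1, sm$structure, lambda = sm$params$lambda,
                       init = sm$params,
                       ref_blood_fractions = sm$params$blood_fractions,
                       seed = 4, control = list(n_temps = 5, steps = 5))
  expect_equal(f1$wrss, f2$wrss, tolerance = 1e-6)

  # lifting ties can only improve (or match) the combined objective
  tied <- fit_joint(list(ds1, ds2), sm$structure, free = character(),
                    lambda = sm$params$lambda, init = sm$params,
                    ref_blood_fractions = sm$params$blood_fractions,
                    seed = 5, control = list(n_temps = 10, steps = 15))
  expect_lte(jf$wrss, tied$wrss + 1e-9)
  expect_error(fit_joint(list(ds1), sm$structure,
                         free = c("k_blood_fast", "k_blood_fast"),
                         lambda = sm$params$lambda),
               "overlap")
})
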