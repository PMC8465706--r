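test_that("rate matrix encodes transfers, decay and conservation", {
  dm <- decay_only_model(lambda = 0.1)
  M <- build_rate_matrix(dm$structure, dm$params)
  expect_equal(unname(M), matrix(-0.1), tolerance = 1e-15)

  # two compartments, no decay: columns sum to zero (mass conserving)
  st <- model_structure(c("blood", "t1"),
                        data.frame(from = "blood", to = "t1"))
  M2 <- build_rate_matrix(st, parameter_set(c(k_blood_t1 = 0.3), lambda = 0))
  expect_equal(unname(colSums(M2)), c(0, 0), tolerance = 1e-15)
  expect_equal(M2["t1", "blood"], 0.3)

  # full model: 17 x 17, column sums exactly -lambda
  m <- clr_final_model()
  p <- clr_reference_parameters()
  M17 <- build_rate_matrix(m, p)
  expect_equal(dim(M17), c(17L, 17L))
  expect_equal(unname(colSums(M17)), rep(-p$lambda, 17), tolerance = 1e-12)

  # missing rate is a configuration error naming the edge
  bad <- parameter_set(p$rates[-1], p$blood_fractions, p$lambda)
  expect_error(build_rate_matrix(m, bad), names(p$rates)[1])
})

test_that("solver matches closed forms and the brute-force exponential", {
  dm <- decay_only_model(lambda = 0.1)
  tr <- solve_activities(dm$structure, dm$params, c(10))
  expect_equal(unname(tr$y[tr$times == 10, "blood"]), 100 * exp(-1),
               tolerance = 1e-12)
  expect_equal(unname(tr$y[1, "blood"]), 100)  # y(0) equals the bolus

  m <- clr_final_model()
  p <- clr_reference_parameters()
  M <- build_rate_matrix(m, p)
  y0 <- stats::setNames(numeric(17), m$compartments)
  y0["blood"] <- 100
  for (t in c(1, 24, 505)) {
    tr <- solve_activities(m, p, t)
    expect_equal(unname(tr$y[2, ]), unname(as.numeric(oracle_expm(M, t) %*% y0)),
                 tolerance = 1e-8)
  }
})

test_that("closed system with no decay conserves total activity", {
  sm <- small_organ_model(lambda = 0)
  tr <- solve_activities(sm$structure, sm$params, c(1, 10, 100, 1000))
  expect_equal(unname(rowSums(tr$y)), rep(100, length(tr$times)),
               tolerance = 1e-8)
})

test_that("mass balance, non-negativity and linearity hold on random systems", {
  for (seed in 1:5) {
    rm <- rand_stable_model(n_tissue = 4, seed = seed)
    lam <- rm$params$lambda
    tr <- solve_activities(rm$structure, rm$params, c(0.5, 5, 50, 200))
    tot <- rowSums(tr$y) * exp(lam * tr$times)
    expect_equal(tot / tot[1], rep(1, length(tot)), tolerance = 1e-8)
    expect_true(all(tr$y >= -1e-9))
    # doubling y0 doubles observables and cumulated activities
    y0 <- stats::setNames(numeric(length(rm$structure$compartments)),
                          rm$structure$compartments)
    y0["blood"] <- 200
    tr2 <- solve_activities(rm$structure, rm$params, c(0.5, 5, 50, 200),
                            y0 = y0)
    expect_equal(tr2$y, 2 * tr$y, tolerance = 1e-10)
    expect_equal(cumulated_activity(rm$structure, rm$params, "organ", y0 = y0),
                 2 * cumulated_activity(rm$structure, rm$params, "organ"),
                 tolerance = 1e-10)
  }
})

test_that("organ observables combine member compartments and blood fraction", {
  m <- clr_final_model()
  p <- clr_reference_parameters()
  tr <- solve_activities(m, p, c(5, 24))
  # at t = 0 everything is in blood: observable is f * 100
  expect_equal(organ_activity(tr, m, p, "heart_wall")[1],
               p$blood_fractions[["f_heart_wall"]] * 100,
               tolerance = 1e-12)
  # tumor blood fraction is negligible: sum of fast + slow only
  tum <- organ_activity(tr, m, p, "tumor")
  expect_equal(tum, unname(tr$y[, "tumor_fast"] + tr$y[, "tumor_slow"]),
               tolerance = 1e-12)
  expect_error(organ_activity(tr, m, p, "brain"), "unknown organ")

  # empty compartment set with zero fraction observes nothing
  st <- model_structure(
    c("blood", "t1"), data.frame(from = "blood", to = "t1"),
    list(void = list(compartments = character(), blood_fraction = NA)))
  ps <- parameter_set(c(k_blood_t1 = 0.1), lambda = 0.01)
  tr0 <- solve_activities(st, ps, c(1, 10))
  expect_equal(organ_activity(tr0, st, ps, "void"), rep(0, 3))
})

test_that("cumulated activity: closed form, quadrature and divergence", {
  dm <- decay_only_model(lambda = 0.05)
  expect_equal(unname(cumulated_activity(dm$structure, dm$params, "blood")),
               100 / 0.05, tolerance = 1e-12)

  for (seed in 1:5) {
    rm <- rand_stable_model(n_tissue = 4, seed = 10 + seed)
    closed <- cumulated_activity(rm$structure, rm$params, "organ")
    quad <- oracle_cumact_quadrature(rm$structure, rm$params, "organ")
    expect_equal(unname(closed), quad, tolerance = 1e-6)
  }

  # lambda = 0 with a closed system diverges
  sm <- small_organ_model(lambda = 0)
  expect_error(cumulated_activity(sm$structure, sm$params, "organ"),
               "diverges")
})

test_that("blood-contribution share is the blood term over the total", {
  sm <- small_organ_model()
  share <- blood_contribution_share(sm$structure, sm$params, "organ")
  M <- build_rate_matrix(sm$structure, sm$params)
  y0 <- c(100, 0, 0)
  integral <- solve(M, -y0)
  manual <- 100 * sm$params$blood_fractions[["f_organ"]] * integral[1] /
    cumulated_activity(sm$structure, sm$params, "organ")
  expect_equal(share, unname(manual), tolerance = 1e-12)
  expect_error(blood_contribution_share(sm$structure, sm$params, "blood"),
               "blood-fraction")
})
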