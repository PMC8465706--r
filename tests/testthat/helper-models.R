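# small fixture models and independent oracles, built in code

# one compartment, pure decay
decay_only_model <- function(lambda = 0.1) {
  st <- model_structure("blood", data.frame(from = character(),
                                            to = character()),
                        list(blood = list(compartments = "blood",
                                          blood_fraction = NA)))
  list(structure = st, params = parameter_set(numeric(), lambda = lambda))
}

# blood <-> tissue fast -> slow, one observed organ; truth rates chosen
# on the scale of the published values
small_organ_model <- function(lambda = decay_constant("I131"),
                              k_in = 0.05, k_out = 0.4, k_fs = 0.01,
                              f = 0.03) {
  st <- model_structure(
    c("blood", "fast", "slow"),
    data.frame(from = c("blood", "fast", "fast"),
               to = c("fast", "blood", "slow")),
    list(organ = list(compartments = c("fast", "slow"),
                      blood_fraction = "f_organ"),
         blood = list(compartments = "blood", blood_fraction = NA)))
  pars <- parameter_set(c(k_blood_fast = k_in, k_fast_blood = k_out,
                          k_fast_slow = k_fs),
                        c(f_organ = f), lambda)
  list(structure = st, params = pars)
}

# random strictly stable compartmental system with one observed organ
rand_stable_model <- function(n_tissue = 4, seed = 1) {
  set.seed(seed)
  comps <- c("blood", paste0("c", seq_len(n_tissue)))
  edges <- data.frame(from = "blood", to = comps[-1],
                      stringsAsFactors = FALSE)
  back <- sample(comps[-1], max(1, n_tissue %/% 2))
  edges <- rbind(edges, data.frame(from = back, to = "blood"))
  st <- model_structure(
    comps, edges,
    list(organ = list(compartments = comps[2], blood_fraction = "f_organ"),
         blood = list(compartments = "blood", blood_fraction = NA)))
  rates <- stats::setNames(stats::runif(nrow(st$edges), 0.01, 0.6),
                           st$edges$rate)
  pars <- parameter_set(rates, c(f_organ = stats::runif(1, 0, 0.1)),
                        lambda = stats::runif(1, 0.01, 0.1))
  list(structure = st, params = pars)
}

# independent brute-force matrix exponential: plain truncated Taylor
# series with step halving (no shared code with the package's solver)
oracle_expm <- function(M, t) {
  nrm <- max(colSums(abs(M * t)))
  s <- max(0, ceiling(log2(max(nrm, 1))) + 1)
  A <- M * (t / 2^s)
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:40) {
    term <- term %*% A / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# quadrature oracle for cumulated activity of one organ
oracle_cumact_quadrature <- function(structure, params, organ) {
  f <- function(tv) {
    vapply(tv, function(t) {
      if (t == 0) tr <- solve_activities(structure, params, c(0, 1e-9))
      else tr <- solve_activities(structure, params, t)
      utils::tail(organ_activity(tr, structure, params, organ), 1)
    }, numeric(1))
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12)$value
}
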