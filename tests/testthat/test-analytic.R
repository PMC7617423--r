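test_that("case weights follow the coalescent waiting-time closed forms", {
  # deep true-false split: lineage sorting essentially always completes
  w <- case_weights(baseline_params())
  expect_equal(unname(w["w_case1"]), 1 - exp(-20), tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # waiting interval of exactly 2N generations
  w <- case_weights(model_params(T_tf = 20000, N = 10000))
  expect_equal(unname(w["w_case1"]), 1 - exp(-1), tolerance = 1e-12)

  # near-simultaneous splits: the three subcases approach 1/3 each
  w <- case_weights(model_params(T_tf = 400000, T_qt = 400000 - 1e-6))
  expect_lt(unname(w["w_case1"]), 1e-9)
  expect_equal(unname(w["w_case21"]), 1 / 3, tolerance = 1e-9)
  expect_equal(unname(w["w_case22"]), unname(w["w_case23"]))

  # the query-true pair becomes joinable only once both samples exist
  w_aged <- case_weights(model_params(T_tf = 400000, T_qt = 50000,
                                      A_q = 30000, A_t = 10000))
  expect_equal(unname(w_aged["w_case1"]),
               1 - exp(-(400000 - 50000) / 20000), tolerance = 1e-12)
})

test_that("without mutations every read is a tie", {
  p <- model_params(T_tf = 400000, mu_site = 0)
  for (id in c(1, 21, 22, 23)) {
    cp <- case_probability(p, id, "least_mismatch")
    expect_equal(probs_vec(cp), c(0, 0, 1), tolerance = 1e-12)
  }
  ap <- assignment_probabilities(p, "least_mismatch")
  expect_equal(probs_vec(ap), c(0, 0, 1), tolerance = 1e-9)
})

test_that("the discordant-branch case 2.2 is exactly symmetric at zero ages", {
  # with true-false coalescing first, the query is equidistant from both
  cp <- case_probability(baseline_params(), 22, "least_mismatch")
  expect_equal(cp$p_correct, cp$p_incorrect, tolerance = 1e-12)
})

test_that("case integrals match direct integration of the printed densities", {
  # Independent route: nested adaptive quadrature of the unnormalized
  # time density over the raw (t1, t2) domain, divided by the printed
  # normalizing constant, with the age-generalized integrand.
  p <- model_params(T_tf = 30000, T_qt = 5000, N = 10000, mu_site = 1e-8,
                    read_length = 96, A_q = 2000, A_t = 1000, A_f = 4000)
  twoN <- 2 * p$N
  T <- p$T_tf
  mu <- p$mu_read
  hi <- T + 50 * twoN   # upper cutoff; truncated tail mass < 2e-11 relative
  dens <- function(ta, tb) exp(-ta / twoN) * exp(-tb / twoN) / twoN^2
  pg <- function(la, lb) poisson_greater_prob(la, lb, tol = 1e-12)
  outer_int <- function(f, lo, up) {
    integrate(function(x) vapply(x, f, 0), lo, up,
              rel.tol = 1e-9, abs.tol = 1e-13)$value
  }

  # Case 1: t1 on [T_qt, T], t2 on [T, inf)
  num <- outer_int(function(t1) {
    outer_int(function(t2) dens(t1, t2) *
                pg(mu * (2 * t2 - t1 - p$A_f), mu * (t1 - p$A_t)), T, hi)
  }, p$T_qt, T)
  den <- exp(-T / twoN) * (exp(-p$T_qt / twoN) - exp(-T / twoN))
  expect_equal(case_probability(p, 1, "least_mismatch")$p_correct,
               num / den, tolerance = 1e-5)

  den2 <- exp(-T / p$N) / 2
  # Case 2.1: T <= t1 < t2
  num <- outer_int(function(t1) {
    outer_int(function(t2) dens(t1, t2) *
                pg(mu * (2 * t2 - t1 - p$A_f), mu * (t1 - p$A_t)), t1, hi)
  }, T, hi)
  expect_equal(case_probability(p, 21, "least_mismatch")$p_correct,
               num / den2, tolerance = 1e-5)

  # Case 2.2: T <= t2 < t1; only t2 enters the mutation comparison
  num <- outer_int(function(t2) {
    outer_int(function(t1) dens(t1, t2), t2, hi) *
      pg(mu * (t2 - p$A_f), mu * (t2 - p$A_t))
  }, T, hi)
  expect_equal(case_probability(p, 22, "least_mismatch")$p_correct,
               num / den2, tolerance = 1e-5)

  # Case 2.3: T <= t3 < t1, ILS topology
  num <- outer_int(function(t3) {
    outer_int(function(t1) dens(t1, t3) *
                pg(mu * (t3 - p$A_f), mu * (2 * t1 - t3 - p$A_t)), t3, hi)
  }, T, hi)
  expect_equal(case_probability(p, 23, "least_mismatch")$p_correct,
               num / den2, tolerance = 1e-5)
})

test_that("probability triples conserve mass for both rules", {
  sets <- c(agreement_params(),
            list(inc = baseline_params(C_t = 0.6, C_f = 0.8),
                 one_sided = baseline_params(C_t = 1, C_f = 0.3)))
  for (p in sets) {
    for (rule in c("least_mismatch", "exact_match")) {
      ap <- assignment_probabilities(p, rule)
      expect_true(all(probs_vec(ap) >= -1e-9))
      expect_equal(sum(probs_vec(ap)), 1, tolerance = 1e-6)
    }
  }
})

test_that("exact match is uniformly more conservative than least mismatch", {
  for (p in agreement_params()) {
    lm <- assignment_probabilities(p, "least_mismatch")
    em <- assignment_probabilities(p, "exact_match")
    expect_lte(em$p_correct, lm$p_correct + 1e-9)
  }
})

test_that("completeness adjustment follows the three-alignment-case mixture", {
  p <- baseline_params()
  full <- assignment_probabilities(p, "least_mismatch")
  # C_t = 0.5, C_f = 1: read aligns to both w.p. 0.5, only-false w.p. 0.5
  half <- assignment_probabilities(baseline_params(C_t = 0.5, C_f = 1),
                                   "least_mismatch")
  expect_equal(half$p_correct, 0.5 * full$p_correct, tolerance = 1e-6)
  expect_equal(half$p_incorrect, 0.5 * full$p_incorrect + 0.5,
               tolerance = 1e-6)

  # vanishing false-reference completeness: reads can only go to true
  tiny <- assignment_probabilities(baseline_params(C_t = 1, C_f = 1e-9),
                                   "least_mismatch")
  expect_gt(tiny$p_correct, 1 - 1e-6)

  # exact match still demands zero mismatches on a single alignment,
  # so its single-alignment gain is strictly smaller
  em_zero <- assignment_probabilities(baseline_params(C_t = 1, C_f = 0.5),
                                      "exact_match")
  em_always <- assignment_probabilities(baseline_params(C_t = 1, C_f = 0.5),
                                        "exact_match",
                                        exact_single_alignment = "always_assign")
  expect_lt(em_zero$p_correct, em_always$p_correct)
  expect_equal(sum(probs_vec(em_zero)), 1, tolerance = 1e-6)
  expect_equal(sum(probs_vec(em_always)), 1, tolerance = 1e-6)
})

test_that("assignment probabilities are invariant under time rescaling", {
  p <- baseline_params(T_qt = 50000, A_q = 20000, C_t = 0.9)
  ref <- assignment_probabilities(p, "least_mismatch")
  for (f in c(2, 10, 100)) {
    sc <- assignment_probabilities(rescale_params(p, f), "least_mismatch")
    expect_equal(probs_vec(sc), probs_vec(ref), tolerance = 1e-6)
  }
  # large-N evaluation via rescaling agrees with direct evaluation
  big <- model_params(T_tf = 4e6, N = 1e6, mu_site = 1e-8, read_length = 96)
  direct <- assignment_probabilities(big, "least_mismatch")
  scaled <- assignment_probabilities(rescale_params(big, 100), "least_mismatch")
  expect_equal(probs_vec(scaled), probs_vec(direct), tolerance = 1e-6)
})

test_that("skipping the lineage-sorting cases is a bounded approximation", {
  p <- baseline_params()   # (T_tf - T_qt)/2N = 20
  full <- assignment_probabilities(p, "least_mismatch")
  approx <- assignment_probabilities(p, "least_mismatch",
                                     skip_ils_cases = TRUE)
  bound <- exp(-(p$T_tf - p$T_qt) / (2 * p$N))
  expect_lt(max(abs(probs_vec(full) - probs_vec(approx))), bound + 1e-9)
})

test_that("the ratio responds to each parameter in the expected direction", {
  base <- baseline_params()
  r_of <- function(sw) sw$ratio
  expect_true(all(diff(r_of(sweep_parameter(base, "N",
                                            c(1e3, 1e4, 1e5)))) < 0))
  expect_true(all(diff(r_of(sweep_parameter(base, "T_tf",
                                            c(2e5, 4e5, 8e5)))) > 0))
  expect_true(all(diff(r_of(sweep_parameter(base, "T_qt",
                                            c(0, 2e4, 5e4)))) < 0))
  expect_true(all(diff(r_of(sweep_parameter(base, "read_length",
                                            c(30, 96, 200)))) > 0))
})

test_that("sweep output is tidy and handles the empty grid", {
  sw <- sweep_parameter(baseline_params(), "N", c(1e3, 1e4))
  expect_named(sw, c("parameter", "value", "rule", "p_correct",
                     "p_incorrect", "p_none", "ratio"))
  expect_equal(nrow(sw), 2L)
  empty <- sweep_parameter(baseline_params(), "N", numeric())
  expect_equal(nrow(empty), 0L)
  expect_named(empty, names(sw))
  expect_error(sweep_parameter(baseline_params(), "mu_read", 1), "vary")
})

test_that("correct-per-incorrect ratio edge semantics", {
  expect_equal(correct_per_incorrect(list(p_correct = 0.5,
                                          p_incorrect = 0.25)), 2)
  expect_identical(correct_per_incorrect(list(p_correct = 0.1,
                                              p_incorrect = 0)), Inf)
  expect_error(correct_per_incorrect(list(p_correct = 0, p_incorrect = 0)),
               "undefined")
})
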