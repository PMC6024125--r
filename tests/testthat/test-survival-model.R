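test_that("adult survival closed forms", {
  ps <- parameter_set(phi_a = 0.78)
  expect_equal(adult_survival_prob(ps), 0.78)
  expect_equal(adult_survival_prob(ps, interval_fraction = 0.5),
               0.78^0.5)
  expect_equal(round(adult_survival_prob(ps, interval_fraction = 0.5), 4),
               0.8832)
  # beta_sex = delta_trans = 0: sexes identical
  expect_equal(adult_survival_prob(ps, "male"),
               adult_survival_prob(ps, "female"))
  ps2 <- parameter_set(phi_a = 0.78, beta_sex = 0.4, delta_trans = -0.3)
  expect_gt(adult_survival_prob(ps2, "male"),
            adult_survival_prob(ps2, "female"))
  expect_lt(adult_survival_prob(ps2, is_first_interval = TRUE),
            adult_survival_prob(ps2))
  expect_error(adult_survival_prob(ps, interval_fraction = 0), "interval_fraction")
  expect_error(adult_survival_prob(ps, interval_fraction = 1.5), "interval_fraction")
})

test_that("juvenile survival closed forms and bounds", {
  ps <- parameter_set(phi_j_mean = 0.25)
  expect_equal(juvenile_survival_prob(ps), 0.25)
  ps2 <- parameter_set(phi_j_mean = 0.25, gamma_band = 0.8)
  expect_gt(juvenile_survival_prob(ps2, banding_method = "fledgling"),
            juvenile_survival_prob(ps2, banding_method = "nestling"))
  expect_error(juvenile_survival_prob(ps, banding_method = "adultish"),
               "unknown banding method")
  # deviates spanning the fitted annual range reproduce it exactly
  ps3 <- parameter_set(phi_j_mean = 0.25, sigma_year_j = 1,
                       eps_year_j = qlogis(c(0.14, 0.38)) - qlogis(0.25))
  expect_equal(juvenile_survival_prob(ps3, year_index = 0), 0.14)
  expect_equal(juvenile_survival_prob(ps3, year_index = 1), 0.38)
  expect_error(juvenile_survival_prob(ps3, year_index = 5), "year_index")
})

test_that("frozen likelihood examples from the enumeration oracle", {
  h <- capture_history(matrix(c(1, 0, 1), 1, 3),
                       individuals("a", "female", "translocated",
                                   "not-applicable", 0L),
                       first_interval_fraction = 1)
  ps <- parameter_set(phi_a = 0.5, p = 0.5)
  # survive+miss+survive+seen: 0.5^4 = 0.0625 (frozen from the oracle)
  expect_equal(cjs_enumeration_oracle(h, ps), log(0.0625), tolerance = 1e-12)
  expect_equal(cjs_marginal_loglik(h, ps), log(0.0625), tolerance = 1e-12)

  # certain survival and detection: the all-ones history has likelihood 1
  h2 <- capture_history(matrix(1, 1, 2),
                        individuals("a", "female", "translocated",
                                    "not-applicable", 0L),
                        first_interval_fraction = 1)
  sure <- parameter_set(phi_a = 1 - 1e-12, p = 1 - 1e-12)
  expect_lt(abs(cjs_marginal_loglik(h2, sure)), 1e-9)

  # a resighting when p -> 0 is (numerically) impossible
  blind <- parameter_set(phi_a = 0.9, p = 1e-12)
  expect_lt(cjs_marginal_loglik(h, blind), -20)

  # single-occasion history: conditioning on first capture leaves nothing
  h3 <- capture_history(matrix(1, 1, 1),
                        individuals("a", "female", "translocated",
                                    "not-applicable", 0L),
                        first_interval_fraction = 1)
  expect_equal(cjs_marginal_loglik(h3, ps), 0)
  expect_equal(cjs_enumeration_oracle(h3, ps), 0)
})

test_that("marginal likelihood equals enumeration on random instances", {
  set.seed(99)
  for (r in 1:100) {
    inst <- random_cjs_instance(n = sample(1:4, 1), T = sample(2:8, 1))
    expect_equal(cjs_marginal_loglik(inst$ch, inst$params, inst$density_j),
                 cjs_enumeration_oracle(inst$ch, inst$params, inst$density_j),
                 tolerance = 1e-10)
  }
  expect_error(
    cjs_enumeration_oracle(small_sim(seed = 1, n_years = 11)$capture_history,
                           parameter_set()),
    "12 occasions")
})

test_that("likelihood is invariant to permuting individuals", {
  set.seed(5)
  inst <- random_cjs_instance(n = 6, T = 6)
  ll <- cjs_marginal_loglik(inst$ch, inst$params)
  perm <- sample(6)
  ch2 <- capture_history(inst$ch$detections[perm, ],
                         inst$ch$individuals[perm, ],
                         occasions = inst$ch$occasions,
                         first_interval_fraction =
                           inst$ch$first_interval_fraction)
  expect_equal(cjs_marginal_loglik(ch2, inst$params), ll, tolerance = 1e-12)
})

test_that("raising p never hurts an all-detected history", {
  h <- capture_history(matrix(1, 2, 5),
                       individuals(c("a", "b"), c("male", "female"),
                                   "translocated", "not-applicable",
                                   c(0L, 0L)),
                       first_interval_fraction = 1)
  lls <- vapply(seq(0.1, 0.95, by = 0.05), function(p)
    cjs_marginal_loglik(h, parameter_set(phi_a = 0.8, p = p)), numeric(1))
  expect_true(all(diff(lls) > 0))
})
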