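test_that("deterministic limit: immortal, always-detected, non-breeding", {
  eps <- 1e-9
  truth <- parameter_set(phi_a = 1 - eps, phi_j_mean = 0.5, p = 1 - eps,
                         alpha_f = -30)
  spec <- scenario_spec(
    data.frame(occasion = 0L, sex = c("male", "female"), count = c(5L, 5L)),
    n_years = 2, truth = truth, seed = 7, unbanded_fraction = 0)
  sim <- simulate_population(spec)
  expect_false(sim$extinct)
  expect_true(all(sim$capture_history$detections == 1))
  expect_true(all(sim$truth_abundance == 10))
  expect_equal(nrow(sim$fecundity), 10)  # 5 females x 2 seasons, all zeros
  expect_true(all(sim$fecundity$fledglings == 0))
})

test_that("fixed seed gives bit-identical output; seeds differ otherwise", {
  a <- small_sim(seed = 11)
  b <- small_sim(seed = 11)
  c <- small_sim(seed = 12)
  expect_identical(a$capture_history$detections,
                   b$capture_history$detections)
  expect_identical(a$fecundity, b$fecundity)
  expect_identical(a$truth$eps_year_j, b$truth$eps_year_j)
  expect_false(identical(a$capture_history$detections,
                         c$capture_history$detections))
})

test_that("empirical event rates match truth within 3 Monte-Carlo SEs", {
  # adult survival and resighting: big non-breeding cohort
  truth <- parameter_set(phi_a = 0.78, phi_j_mean = 0.25, p = 0.9,
                         alpha_f = -30)
  spec <- scenario_spec(
    data.frame(occasion = 0L, sex = c("male", "female"),
               count = c(2500L, 2500L)),
    n_years = 4, truth = truth, seed = 5, unbanded_fraction = 0,
    first_interval_fraction = 1)
  sim <- simulate_population(spec)
  N <- sim$truth_abundance
  exposures <- sum(N[-length(N)])
  expect_gt(exposures, 1e4)
  phi_hat <- sum(N[-1]) / exposures
  se <- sqrt(0.78 * 0.22 / exposures)
  expect_lt(abs(phi_hat - 0.78), 3 * se)
  # resighting: occasions after entry (entry detection is forced)
  det <- sim$capture_history$detections
  first <- sim$capture_history$individuals$first_occasion
  seen <- sum(det[, -1])
  trials <- sum(N[-1])
  p_hat <- seen / trials
  expect_lt(abs(p_hat - 0.9), 3 * sqrt(0.9 * 0.1 / trials))

  # fecundity: many females, immortal adults, no recruitment noise sources
  truth2 <- parameter_set(phi_a = 1 - 1e-9, phi_j_mean = 0.25, p = 0.9,
                          alpha_f = log(3.8), sigma_female = 0)
  spec2 <- scenario_spec(
    data.frame(occasion = 0L, sex = c("male", "female"),
               count = c(2000L, 2000L)),
    n_years = 2, truth = truth2, seed = 6, unbanded_fraction = 1,
    first_interval_fraction = 1)
  sim2 <- simulate_population(spec2)
  k <- sim2$fecundity$fledglings
  expect_gt(length(k), 1000)
  expect_lt(abs(mean(k) - 3.8), 3 * sqrt(3.8 / length(k)))

  # juvenile recruitment: immortal adults, so growth is recruitment
  recruits <- sim2$truth_abundance[3] - sim2$truth_abundance[2]
  fledged_1 <- sum(sim2$fecundity$fledglings[sim2$fecundity$year == 1])
  sj_hat <- recruits / fledged_1
  expect_lt(abs(sj_hat - 0.25), 3 * sqrt(0.25 * 0.75 / fledged_1))
})

test_that("truth abundance bounds the birds seen at each survey", {
  for (s in 1:5) {
    sim <- small_sim(seed = s)
    expect_true(all(sim$truth_abundance >=
                      census_detections(sim$capture_history)))
  }
})

test_that("Tawharanui preset states the documented world", {
  pr <- tawharanui_preset()
  expect_equal(pr$truth$phi_a, 0.78)
  expect_equal(pr$truth$p, 0.90)
  expect_equal(exp(pr$truth$alpha_f), 3.8)
  expect_equal(sum(pr$release$count), 25)
  expect_equal(pr$n_years, 9)
  expect_equal(pr$first_interval_fraction, 0.5)
  dd <- tawharanui_preset(density_dependent = TRUE)
  expect_equal(exp(dd$truth$alpha_f), 4.8)
  # slope calibrated so expected fecundity at 80 birds is 3.3
  expect_equal(expected_fecundity(dd$truth, density = 80), 3.3)
})

test_that("replicate-mean trajectory matches the branching-process oracle", {
  # oracle: two-class expectation recursion E[N'] = phi_a E[N] +
  # E[s_j] f_marg E[N_f], with E over the year deviate computed by
  # quadrature and the founders' half-year first interval included
  truth <- tawharanui_preset()$truth
  Es_j <- integrate(function(e) plogis(qlogis(truth$phi_j_mean) + e) *
                      dnorm(e, 0, truth$sigma_year_j), -Inf, Inf)$value
  f_marg <- exp(truth$alpha_f + truth$sigma_female^2 / 2)
  n_years <- 5
  Nf <- 7 * truth$phi_a^0.5 + 4
  Nm <- 14 * truth$phi_a^0.5
  for (s in seq_len(n_years)) {
    rec <- Es_j * f_marg * Nf / 2
    Nf <- Nf * truth$phi_a + rec
    Nm <- Nm * truth$phi_a + rec
  }
  oracle <- Nf + Nm

  R <- 60
  finals <- vapply(seq_len(R), function(s)
    tail(simulate_population(tawharanui_preset(seed = 1000 + s,
                                               n_years = n_years))
         $truth_abundance, 1), numeric(1))
  se <- sd(finals) / sqrt(R)
  expect_lt(abs(mean(finals) - oracle), 4 * se)
  # same order of magnitude as a real release of this size
  expect_gt(mean(finals), 20)
  expect_lt(mean(finals), 400)
})

test_that("extinction truncates the data with a flag, not an error", {
  truth <- parameter_set(phi_a = 0.01, phi_j_mean = 0.01, p = 0.9,
                         alpha_f = -30)
  spec <- scenario_spec(
    data.frame(occasion = 0L, sex = c("male", "female"), count = c(3L, 3L)),
    n_years = 6, truth = truth, seed = 2)
  sim <- simulate_population(spec)
  expect_true(sim$extinct)
  expect_lt(n_occasions(sim$capture_history), 8)
  expect_equal(tail(sim$truth_abundance, 1), 0)
})
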