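# independent enumeration oracle for P(alive at t | history): enumerate
# state sequences exactly as in the brute-force likelihood and average
alive_marginal_oracle <- function(det, first, phi, p) {
  T <- length(det)
  m <- T - 1 - first
  num <- numeric(T)
  den <- 0
  for (code in 0:(2^max(m, 0) - 1)) {
    states <- c(1L, if (m > 0) as.integer(intToBits(code)[seq_len(m)]))
    pr <- 1
    for (s in seq_len(m)) {
      occ <- first + s
      from <- states[s]; to <- states[s + 1]
      trans <- if (from == 1) (if (to == 1) phi[occ] else 1 - phi[occ])
               else (if (to == 1) 0 else 1)
      emit <- if (to == 1) (if (det[occ + 1] == 1) p[occ + 1] else
                              1 - p[occ + 1])
              else (if (det[occ + 1] == 1) 0 else 1)
      pr <- pr * trans * emit
    }
    den <- den + pr
    idx <- first + which(states == 1L)  # 1-based occasions alive
    num[idx] <- num[idx] + pr
  }
  num / den
}

test_that("forward-backward alive marginals match enumeration", {
  set.seed(21)
  for (r in 1:30) {
    T <- sample(3:7, 1)
    first <- sample(0:(T - 2), 1)
    det <- integer(T)
    det[first + 1] <- 1L
    if (first + 2 <= T)
      det[(first + 2):T] <- rbinom(T - first - 1, 1, 0.5)
    phi <- runif(T - 1, 0.2, 0.95)
    p <- runif(T, 0.2, 0.95)
    got <- cjs_alive_marginals_cpp(matrix(det, 1), first,
                                   matrix(phi, 1), p)
    want <- alive_marginal_oracle(det, first, phi, p)
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
  }
})

test_that("certain detection and survival pin the banded count", {
  h <- capture_history(matrix(1, 4, 3),
                       individuals(sprintf("i%d", 1:4),
                                   c("male", "male", "female", "female"),
                                   "translocated", "not-applicable",
                                   rep(0L, 4)),
                       first_interval_fraction = 1)
  sure <- parameter_set(phi_a = 1 - 1e-12, p = 1 - 1e-12)
  b <- banded_alive(history = h, params = sure)
  expect_equal(as.numeric(b$total), rep(4, 3))
  expect_equal(as.numeric(b$male), rep(2, 3))
  # release occasion: founders are conditioned in
  b2 <- banded_alive(history = h, params = parameter_set(phi_a = 0.5, p = 0.5))
  expect_equal(b2$total[1, 1], 4)
})

test_that("Horvitz-Thompson unbanded correction", {
  cnt <- unbanded_counts(1L, "male", 10L)
  expect_equal(unbanded_estimate(cnt, p_draws = 1, n_occasions = 3)
               $male[1, 2], 10)
  expect_equal(unbanded_estimate(cnt, p_draws = 0.5, n_occasions = 3)
               $male[1, 2], 20)
  none <- unbanded_counts()
  u0 <- unbanded_estimate(none, p_draws = c(0.5, 0.9), n_occasions = 3)
  expect_true(all(u0$total == 0))
  expect_warning(
    unbanded_estimate(cnt, p_draws = c(0, 0.5), n_occasions = 3),
    "p = 0")
})

test_that("total abundance composes and reduces correctly", {
  sim <- small_sim(seed = 8)
  cfg <- fast_mcmc(iterations = 2500, burn_in = 600, seed = 3)
  fit <- fit_ipm(sim, uninformative_priors(), cfg, on_nonconvergence = "none")
  b <- banded_alive(fit, n_draws = 50)
  tot_b <- total_abundance(b)
  # zero unbanded everywhere: total equals the banded component
  expect_equal(attr(tot_b, "draws")$total, b$total)
  ab <- estimate_abundance(fit, n_draws = 50)
  dr <- attr(ab, "draws")
  # combined = male + female + unknown exactly, per draw and occasion
  expect_equal(dr$total, dr$male + dr$female + dr$unknown, tolerance = 1e-12)
  # every draw's total bounds the census sightings
  seen <- census_detections(sim$capture_history)
  expect_true(all(sweep(dr$total, 2, seen) >= -1e-9))
  # mismatched occasions are refused
  u <- unbanded_estimate(unbanded_counts(1L, "male", 3L),
                         p_draws = rep(0.9, nrow(b$total)), n_occasions = 3)
  expect_error(total_abundance(b, u), "different occasions")
  expect_error(unbanded_estimate(unbanded_counts(5L, "male", 3L),
                                 p_draws = 0.9, n_occasions = 3),
               "occasion")
})

test_that("posterior-mean abundance tracks simulation truth", {
  sim <- small_sim(seed = 8)
  cfg <- fast_mcmc(iterations = 4000, burn_in = 1000, seed = 4)
  fit <- fit_ipm(sim, uninformative_priors(), cfg, on_nonconvergence = "warn")
  ab <- estimate_abundance(fit, n_draws = 100)
  tot <- ab$series[ab$series$sex == "total", ]
  err <- abs(tot$mean - sim$truth_abundance) /
    pmax(sim$truth_abundance, 1)
  expect_lt(mean(err), 0.15)
})
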