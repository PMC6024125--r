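# Shared fixtures, all built in code.

# hand-written 3-individual, 4-occasion toy dataset
toy_dataset <- function() {
  det <- rbind(c(1, 0, 1, 0),
               c(0, 1, 1, 1),
               c(0, 1, 0, 0))
  ind <- individuals(c("f01", "m01", "w01"),
                     c("female", "male", "unknown"),
                     c("translocated", "translocated", "wild-born"),
                     c("not-applicable", "not-applicable", "nestling"),
                     c(0L, 1L, 1L))
  ch <- capture_history(det, ind, first_interval_fraction = 0.5)
  fec <- fecundity_records("f01", c(1L, 2L), c(3L, 5L), c(10, 12))
  unb <- unbanded_counts(c(2L, 3L), c("male", "unknown"), c(2L, 1L))
  list(capture_history = ch, fecundity = fec, unbanded = unb)
}

# a small, quick simulated dataset
small_sim <- function(seed = 1, n_years = 4, density_dependent = FALSE) {
  simulate_population(tawharanui_preset(density_dependent = density_dependent,
                                        seed = seed, n_years = n_years))
}

# the reduced model matching the constant-fecundity generator truth;
# any model_config() argument can be overridden through ...
reduced_config <- function(..., dd = FALSE) {
  base <- list(density_on_fecundity = dd, density_on_juvenile = FALSE,
               sex_on_adult = FALSE, translocation_effect = FALSE,
               banding_age_effect = FALSE, year_re_on_resighting = FALSE,
               year_re_on_fecundity = FALSE)
  do.call(model_config, utils::modifyList(base, list(...)))
}

fast_mcmc <- function(..., iterations = 4000, burn_in = 1000, chains = 2,
                      thin = 4, seed = 42, dd = FALSE) {
  reduced_config(iterations = iterations, burn_in = burn_in, chains = chains,
                 thin = thin, seed = seed, dd = dd, ...)
}

# random CJS instance generator for oracle-equivalence property tests
random_cjs_instance <- function(n = 3, T = 6) {
  first <- sample(0:(T - 2), n, replace = TRUE)
  det <- matrix(0L, n, T)
  for (i in seq_len(n)) {
    det[i, first[i] + 1] <- 1L
    later <- seq(first[i] + 2, T)
    det[i, later[later <= T]] <- rbinom(sum(later <= T), 1, 0.5)
  }
  origin <- sample(c("translocated", "wild-born"), n, replace = TRUE)
  ind <- individuals(sprintf("i%02d", seq_len(n)),
                     sample(c("male", "female", "unknown"), n, TRUE),
                     origin,
                     ifelse(origin == "translocated", "not-applicable",
                            sample(c("nestling", "fledgling"), n, TRUE)),
                     first)
  ch <- capture_history(det, ind,
                        first_interval_fraction = sample(c(0.5, 1), 1))
  params <- parameter_set(
    phi_a = runif(1, 0.2, 0.95), phi_j_mean = runif(1, 0.05, 0.6),
    sigma_year_j = 0.5, eps_year_j = rnorm(T - 1, 0, 0.5),
    beta_dens_j = rnorm(1, 0, 0.1), gamma_band = rnorm(1, 0, 0.5),
    beta_sex = rnorm(1, 0, 0.5), delta_trans = rnorm(1, 0, 0.5),
    p = runif(1, 0.2, 0.95), sigma_year_p = 0.3,
    eps_year_p = rnorm(T, 0, 0.3))
  list(ch = ch, params = params, density_j = runif(T - 1, 0, 3))
}
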