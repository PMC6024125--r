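priors_file <- system.file("extdata", "informative_priors_synthetic.yaml",
                           package = "reintroIPM")

test_that("uninformative defaults are the stated vague choices", {
  ps <- uninformative_priors()
  expect_equal(attr(ps, "mode"), "uninformative")
  expect_equal(ps$p[c("family", "scale", "par1", "par2")],
               list(family = "normal", scale = "logit", par1 = 0, par2 = 10))
  expect_equal(ps$sigma_female[c("family", "par1", "par2")],
               list(family = "uniform", par1 = 0, par2 = 10))
  # logistic transform of normal(0, 10) is symmetric about 0.5
  set.seed(1)
  draws <- sample_prior(ps$p, 2e5)
  expect_lt(abs(median(draws) - 0.5), 0.01)
  expect_lt(abs(mean(draws < 0.5) - 0.5), 0.01)
})

test_that("moment matching reproduces moments and rejects degeneracy", {
  expect_error(moment_match(rep(0.3, 500)), "degenerate")
  expect_error(moment_match(rnorm(50)), "at least 100")
  set.seed(2)
  x <- rnorm(1e5, 1.2, 0.4)
  d <- moment_match(x, "normal")
  expect_identical(d$par1, mean(x))  # exact first two moments
  expect_identical(d$par2, sd(x))
  expect_lt(abs(d$par1 - 1.2), 3 * 0.4 / sqrt(1e5))
  # logit-scale draws with logistic-mean survival 0.78: implied median
  y <- rnorm(1e5, qlogis(0.78), 0.3)
  dm <- moment_match(y, "normal", scale = "logit")
  expect_lt(abs(plogis(dm$par1) - 0.78), 0.005)
  # uniform-sd matches the first moment: upper = twice the sample mean
  z <- abs(rnorm(1000, 0.3, 0.05))
  u <- moment_match(z, "uniform-sd")
  expect_equal(u$family, "uniform")
  expect_equal(u$par2, 2 * mean(z))
})

test_that("informative prior set covers exactly the four derived priors", {
  ps <- informative_priors(priors_file)
  expect_equal(attr(ps, "mode"), "informative")
  expect_equal(ps$phi_a$scale, "logit")
  expect_equal(ps$alpha_f$scale, "log")
  expect_lt(ps$phi_a$par2, 10)        # informative entries are tight
  expect_lt(ps$phi_j$par2, 10)
  expect_equal(ps$beta_sex$par2, 10)  # everything else stays vague
  expect_equal(ps$sigma_year_j$family, "uniform")

  # a file missing one of the four names the gap
  spec <- yaml::read_yaml(priors_file)
  spec$juvenile_survival <- NULL
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(spec, f)
  expect_error(informative_priors(f), "juvenile_survival")
})

test_that("prior-set serialization round trip is exact", {
  ps <- informative_priors(priors_file)
  f <- tempfile(fileext = ".yaml")
  write_prior_set(ps, f)
  back <- read_prior_set(f)
  expect_identical(attr(back, "mode"), "informative")
  for (nm in names(ps))
    expect_identical(ps[[nm]], back[[nm]], label = nm)
})

test_that("prior sampling reproduces stated moments within Monte-Carlo error", {
  set.seed(3)
  u <- sample_prior(uninformative_priors()$sigma_female, 2e5)
  expect_lt(abs(mean(u) - 5), 3 * (10 / sqrt(12)) / sqrt(2e5))
  expect_lt(abs(sd(u) - 10 / sqrt(12)), 0.05)
  ps <- informative_priors(priors_file)
  s <- sample_prior(ps$sigma_female, 2e5)
  expect_lt(abs(mean(s) - 0.30), 3 * 0.10 / sqrt(2e5) + 0.002)
})

test_that("prior-only lambda from the placeholder file is wide", {
  set.seed(4)
  pl <- prior_lambda(informative_priors(priors_file), n = 2e5)
  expect_gt(pl$upper - pl$lower, 0.5)
  expect_lt(abs(pl$mean - 1.08), 0.06)
})
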