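# Canonical parameter keys a prior set must cover, with the link scale each
# prior lives on.  Regression coefficients and intercepts get normal priors
# on the link scale; random-effect SDs get uniform(0, upper) priors unless an
# informative (truncated-normal) prior is supplied.
PRIOR_KEYS <- c(phi_a = "logit", beta_sex = "natural", delta_trans = "natural",
                phi_j = "logit", beta_dens_j = "natural",
                gamma_band = "natural", sigma_year_j = "natural",
                p = "logit", sigma_year_p = "natural",
                alpha_f = "log", beta_dens_f = "natural",
                sigma_female = "natural", sigma_year_f = "natural")

# the four parameters for which data-derived informative priors exist
INFORMATIVE_KEYS <- c(mean_fecundity = "alpha_f",
                      sigma_female = "sigma_female",
                      adult_survival = "phi_a",
                      juvenile_survival = "phi_j")

prior_dist <- function(family = c("normal", "uniform"),
                       scale = c("natural", "logit", "log"),
                       par1, par2) {
  family <- match.arg(family)
  scale <- match.arg(scale)
  if (family == "normal" && par2 <= 0) stop("normal sd must be > 0")
  if (family == "uniform" && par2 <= 0) stop("uniform upper must be > 0")
  structure(list(family = family, scale = scale,
                 par1 = as.numeric(par1), par2 = as.numeric(par2)),
            class = "prior_dist")
}

#' Uninformative default priors
#'
#' Vague conventional choices: normal(0, sd = 10) on the logit/log link scale
#' for every coefficient and intercept, uniform(0, 10) for every
#' random-effect SD.  The logistic transform of normal(0, 10) puts symmetric
#' mass around 0.5, so survival and resighting probabilities are a priori
#' unconstrained.
#'
#' @return an object of class `"prior_set"`: a named list of distributions
#'   with a `mode` attribute.
#' @export
uninformative_priors <- function() {
  ps <- lapply(names(PRIOR_KEYS), function(k) {
    if (startsWith(k, "sigma")) prior_dist("uniform", "natural", 0, 10)
    else prior_dist("normal", PRIOR_KEYS[[k]], 0, 10)
  })
  names(ps) <- names(PRIOR_KEYS)
  structure(ps, mode = "uninformative", class = "prior_set")
}

#' Informative priors from a prior-set file
#'
#' Reads the data-derived predictive distributions for the four parameters
#' that previous-reintroduction data can inform -- mean fecundity, the
#' female-effect SD on log fecundity, annual adult survival and apparent
#' juvenile survival -- and combines them with uninformative defaults for
#' everything else.  The file is YAML with one block per parameter:
#' `{family: normal|uniform, scale: logit|log|natural, par1: .., par2: ..}`.
#'
#' @param path YAML file supplying blocks named `mean_fecundity`,
#'   `sigma_female`, `adult_survival`, `juvenile_survival`.
#' @return a `"prior_set"` with mode `"informative"`.
#' @export
informative_priors <- function(path) {
  spec <- yaml::read_yaml(path)
  missing <- setdiff(names(INFORMATIVE_KEYS), names(spec))
  if (length(missing))
    stop("prior-set file is missing informative priors for: ",
         paste(missing, collapse = ", "))
  ps <- uninformative_priors()
  for (nm in names(INFORMATIVE_KEYS)) {
    b <- spec[[nm]]
    ps[[INFORMATIVE_KEYS[[nm]]]] <-
      prior_dist(b$family, b$scale, b$par1, b$par2)
  }
  attr(ps, "mode") <- "informative"
  ps
}

#' @export
print.prior_set <- function(x, ...) {
  cat("<prior_set> mode:", attr(x, "mode"), "\n")
  for (nm in names(x)) {
    d <- x[[nm]]
    cat(sprintf("  %-12s %s(%g, %g) on %s scale\n", nm, d$family, d$par1,
                d$par2, d$scale))
  }
  invisible(x)
}

#' Serialize / deserialize a prior set
#'
#' YAML round trip is exact: numeric parameters are written in full
#' precision.
#'
#' @param priors a `"prior_set"`.
#' @param path file path.
#' @return `read_prior_set` returns a `"prior_set"`; `write_prior_set`
#'   returns `path` invisibly.
#' @export
write_prior_set <- function(priors, path) {
  out <- lapply(priors, function(d)
    list(family = d$family, scale = d$scale, par1 = d$par1, par2 = d$par2))
  out$mode <- attr(priors, "mode")
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @rdname write_prior_set
#' @export
read_prior_set <- function(path) {
  spec <- yaml::read_yaml(path)
  mode <- spec$mode %||% "uninformative"
  spec$mode <- NULL
  ps <- lapply(spec, function(b) prior_dist(b$family, b$scale, b$par1, b$par2))
  structure(ps, mode = mode, class = "prior_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moment-match predictive draws to a parametric prior
#'
#' Summarizes Monte-Carlo draws of a parameter (on its link scale) into the
#' parametric form the model consumes.  `"normal"` matches the sample mean
#' and SD exactly.  `"uniform-sd"` is for random-effect SDs: it returns
#' uniform(0, upper) with the upper bound set to twice the sample mean, the
#' uniform whose mean matches the draws (a one-parameter family cannot match
#' both moments).
#'
#' @param samples numeric vector of at least 100 draws.
#' @param family `"normal"` or `"uniform-sd"`.
#' @param scale link scale tag carried into the returned distribution.
#' @return a prior distribution usable inside a prior set.
#' @export
moment_match <- function(samples, family = c("normal", "uniform-sd"),
                         scale = "natural") {
  family <- match.arg(family)
  if (length(samples) < 100) stop("need at least 100 draws to moment-match")
  s <- sd(samples)
  if (!is.finite(s) || s == 0)
    stop("degenerate (zero-variance) draws cannot be moment-matched")
  if (family == "normal")
    prior_dist("normal", scale, mean(samples), s)
  else
    prior_dist("uniform", scale, 0, 2 * mean(samples))
}

#' Draw from one prior distribution
#'
#' Samples on the natural scale of the parameter: logit- or log-scale normal
#' priors are transformed back through the inverse link.
#'
#' @param dist a prior distribution (an element of a prior set).
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_prior <- function(dist, n) {
  x <- switch(dist$family,
              normal = rnorm(n, dist$par1, dist$par2),
              uniform = runif(n, dist$par1, dist$par2))
  switch(dist$scale, logit = plogis(x), log = exp(x), natural = x)
}

#' Prior-only distribution of the finite rate of increase
#'
#' Forward Monte Carlo through lambda = s_a + s_j f / 2 using only the prior
#' distributions of adult survival, juvenile survival and mean fecundity --
#' the projection available before any monitoring data exist.
#'
#' @param priors a `"prior_set"`.
#' @param n number of Monte-Carlo draws.
#' @return list with `draws`, `mean`, `lower`, `upper` (95 percent interval).
#' @export
prior_lambda <- function(priors, n = 100000) {
  sa <- sample_prior(priors$phi_a, n)
  sj <- sample_prior(priors$phi_j, n)
  f <- sample_prior(priors$alpha_f, n)
  lam <- sa + 0.5 * sj * f
  list(draws = lam, mean = mean(lam),
       lower = unname(quantile(lam, 0.025)),
       upper = unname(quantile(lam, 0.975)))
}

# Translate a prior_set into the flat (type, p1, p2) vectors the C++ sampler
# consumes, ordered by the sampler's 13-scalar layout.
priors_for_sampler <- function(priors) {
  ord <- c("phi_a", "beta_sex", "delta_trans", "phi_j", "beta_dens_j",
           "gamma_band", "sigma_year_j", "p", "sigma_year_p", "alpha_f",
           "beta_dens_f", "sigma_female", "sigma_year_f")
  type <- p1 <- p2 <- numeric(length(ord))
  for (i in seq_along(ord)) {
    d <- priors[[ord[i]]]
    if (is.null(d)) stop("prior set lacks an entry for ", ord[i])
    type[i] <- if (d$family == "uniform") 1 else 0
    p1[i] <- d$par1
    p2[i] <- d$par2
  }
  list(type = type, p1 = p1, p2 = p2)
}
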