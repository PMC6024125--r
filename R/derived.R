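#' Finite rate of increase from point values
#'
#' The plug-in identity `lambda = s_a + s_j f / 2`: each female's fledglings
#' are split 50:50 by sex, survive to adulthood with probability `s_j`, and
#' adults survive with probability `s_a`.
#'
#' @param s_a annual adult survival probability.
#' @param s_j apparent juvenile survival probability.
#' @param f mean fledglings per female per year.
#' @return lambda.
#' @export
finite_rate_of_increase <- function(s_a, s_j, f) s_a + 0.5 * s_j * f

#' Posterior of the finite rate of increase
#'
#' Applies `lambda = s_a + s_j f / 2` draw by draw, so parameter uncertainty
#' and covariance propagate exactly.  `s_j` is the mean-year juvenile
#' survival (year deviates at zero) and `f` the average-female fecundity
#' `exp(alpha_f + beta_dens_f density)`.  Under a density-dependent
#' fecundity model the default density is 0, i.e. lambda at low density,
#' the persistence question a reintroduction asks.
#'
#' @param fit an `"ipm_fit"`.
#' @param density density at which to evaluate fecundity (only meaningful
#'   under density dependence).
#' @return list with `draws`, `mean`, `lower`, `upper` (95 percent
#'   interval), and the `density` used.
#' @export
derive_lambda <- function(fit, density = NULL) {
  dd <- fit$flags[["densf"]]
  if (is.null(density)) density <- 0
  if (!is.finite(density) || density < 0)
    stop("density must be a non-negative number")
  if (!dd && density != 0)
    warning("model has no density effect on fecundity; density ignored")
  d <- fit$draws
  f <- exp(d[, "alpha_f"] + (if (dd) d[, "beta_dens_f"] * density else 0))
  lam <- plogis(d[, "logit_phi_a"]) + 0.5 * plogis(d[, "logit_phi_j"]) * f
  list(draws = unname(lam), mean = mean(lam),
       lower = unname(quantile(lam, 0.025)),
       upper = unname(quantile(lam, 0.975)),
       density = density)
}

#' Carrying capacity under density-dependent fecundity
#'
#' The population size at which lambda declines to 1:
#' `K = (log(2 (1 - phi_a) / phi_j) - alpha_f) / beta_dens_f`,
#' the closed-form solution of `phi_a + phi_j exp(alpha_f + beta_dens_f K)
#' / 2 = 1`.  Applied per posterior draw; draws with a non-negative density
#' slope or with lambda(0) < 1 have no finite positive K, are flagged
#' undefined and excluded, and their proportion is reported.
#'
#' @param x an `"ipm_fit"` with density-dependent fecundity, or a
#'   [parameter_set()] (or plain list with `phi_a`, `phi_j_mean`, `alpha_f`,
#'   `beta_dens_f`) for a single point evaluation.
#' @return for a fit: list with `draws` (NA where undefined), `mean`,
#'   `lower`, `upper`, `prop_undefined`; for point input: a single K.
#' @export
carrying_capacity <- function(x) {
  K_of <- function(phi_a, phi_j, alpha_f, beta_f) {
    lam0 <- phi_a + 0.5 * phi_j * exp(alpha_f)
    ok <- beta_f < 0 & lam0 >= 1
    K <- rep(NA_real_, length(phi_a))
    K[ok] <- (log(2 * (1 - phi_a[ok]) / phi_j[ok]) - alpha_f[ok]) /
      beta_f[ok]
    K
  }
  if (inherits(x, "ipm_fit")) {
    if (!x$flags[["densf"]])
      stop("carrying capacity requires density-dependent fecundity")
    d <- x$draws
    K <- K_of(plogis(d[, "logit_phi_a"]), plogis(d[, "logit_phi_j"]),
              d[, "alpha_f"], d[, "beta_dens_f"])
    if (all(is.na(K)))
      stop("carrying capacity undefined for every posterior draw")
    list(draws = K, mean = mean(K, na.rm = TRUE),
         lower = unname(quantile(K, 0.025, na.rm = TRUE)),
         upper = unname(quantile(K, 0.975, na.rm = TRUE)),
         prop_undefined = mean(is.na(K)))
  } else {
    K <- K_of(x$phi_a, x$phi_j_mean, x$alpha_f, x$beta_dens_f)
    if (is.na(K)) stop("carrying capacity undefined for these parameters")
    K
  }
}

# fixed effects eligible for removal, and the config flag each belongs to
REDUCIBLE_FIXED <- c(beta_sex = "sex_on_adult",
                     delta_trans = "translocation_effect",
                     gamma_band = "banding_age_effect",
                     beta_dens_j = "density_on_juvenile",
                     beta_dens_f = "density_on_fecundity")
REDUCIBLE_RE <- c(sigma_year_j = "year_re_on_juvenile",
                  sigma_year_p = "year_re_on_resighting",
                  sigma_female = "female_re_on_fecundity",
                  sigma_year_f = "year_re_on_fecundity")

#' One model-reduction pass
#'
#' Drops each active fixed effect whose central 95 percent credible interval
#' contains zero, and each random effect whose link-scale SD has its
#' posterior 25th percentile below `config$re_drop_threshold` (the
#' operational reading of "lower portion of the posterior concentrated near
#' zero").  One pass per call; iterate to a fixed point by refitting.
#'
#' @param fit an `"ipm_fit"` of the model to reduce.
#' @param config configuration to reduce; defaults to the fit's own.
#' @return a new [model_config()] with the dropped effects switched off and
#'   the removals recorded in `attr(, "dropped")`.
#' @export
reduce_model <- function(fit, config = fit$config) {
  d <- fit$draws
  dropped <- character()
  flag_names <- c(sex = "sex_on_adult", trans = "translocation_effect",
                  band = "banding_age_effect", densj = "density_on_juvenile",
                  yrej = "year_re_on_juvenile",
                  yrep = "year_re_on_resighting",
                  densf = "density_on_fecundity",
                  femre = "female_re_on_fecundity",
                  yref = "year_re_on_fecundity")
  for (par in names(REDUCIBLE_FIXED)) {
    cfg_flag <- REDUCIBLE_FIXED[[par]]
    short <- names(flag_names)[flag_names == cfg_flag]
    if (!isTRUE(fit$flags[[short]])) next
    ci <- quantile(d[, par], c(0.025, 0.975))
    if (ci[1] <= 0 && ci[2] >= 0) {
      config[[cfg_flag]] <- FALSE
      dropped <- c(dropped, par)
    }
  }
  for (par in names(REDUCIBLE_RE)) {
    cfg_flag <- REDUCIBLE_RE[[par]]
    short <- names(flag_names)[flag_names == cfg_flag]
    if (!isTRUE(fit$flags[[short]])) next
    if (quantile(d[, par], 0.25) < config$re_drop_threshold) {
      config[[cfg_flag]] <- FALSE
      dropped <- c(dropped, par)
    }
  }
  attr(config, "dropped") <- dropped
  config
}
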