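#' Expected fecundity of a female
#'
#' Poisson mean on the log link:
#' `exp(alpha_f + beta_dens_f density + female_effect + year_effect)`.
#' With random effects at zero this is the average-female, average-year
#' fecundity -- the `f` that enters the finite rate of increase -- not the
#' marginal (population-averaged) mean `exp(alpha_f + sigma^2 / 2)`.
#'
#' @param params a [parameter_set()].
#' @param density density covariate (same scale as `beta_dens_f`).
#' @param female_effect,year_effect log-scale random-effect values.
#' @return expected number of fledglings.
#' @export
expected_fecundity <- function(params, density = 0, female_effect = 0,
                               year_effect = 0) {
  if (any(density < 0)) stop("density must be >= 0")
  exp(params$alpha_f + params$beta_dens_f * density + female_effect +
        year_effect)
}

#' Marginal (population-averaged) mean fecundity
#'
#' `exp(alpha_f + (sigma_female^2 + sigma_year_f^2) / 2)`: the expectation
#' over random female and year draws, exposed alongside the average-female
#' value for completeness.
#'
#' @inheritParams expected_fecundity
#' @return marginal mean fledglings per female.
#' @export
marginal_fecundity <- function(params, density = 0) {
  exp(params$alpha_f + params$beta_dens_f * density +
        (params$sigma_female^2 + params$sigma_year_f^2) / 2)
}

#' Poisson log-likelihood of the fecundity records
#'
#' Sum over records of the Poisson log-pmf at the expected fecundity.  The
#' female effect is looked up in `params$eps_female` by id (an error if
#' absent); the year effect in `params$eps_year_f` by year label, defaulting
#' to zero when no deviates are stored.
#'
#' @param records [fecundity_records()].
#' @param params a [parameter_set()].
#' @return log-likelihood; 0 for an empty record set.
#' @export
fecundity_loglik <- function(records, params) {
  if (!nrow(records)) return(0)
  fe <- rep(0, nrow(records))
  if (params$sigma_female > 0 || length(params$eps_female)) {
    idx <- match(records$female_id, names(params$eps_female))
    if (anyNA(idx))
      stop("no female effect stored for: ",
           paste(unique(records$female_id[is.na(idx)]), collapse = ", "))
    fe <- unname(params$eps_female[idx])
  }
  ye <- rep(0, nrow(records))
  if (length(params$eps_year_f)) {
    idx <- match(as.character(records$year), names(params$eps_year_f))
    ye <- ifelse(is.na(idx), 0, params$eps_year_f[idx])
  }
  mu <- expected_fecundity(params, records$density, fe, ye)
  sum(dpois(records$fledglings, mu, log = TRUE))
}
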