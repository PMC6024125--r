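#' Adult survival probability over one interval
#'
#' `logistic(logit(phi_a) + beta_sex I\[male\] + delta_trans I\[first\])`
#' raised to the power `interval_fraction`, so a six-month interval uses the
#' square root of annual survival.
#'
#' @param params a [parameter_set()].
#' @param sex `"male"`, `"female"` or `"unknown"` (no sex effect applied to
#'   unknowns).
#' @param is_first_interval does the interval follow a translocated bird's
#'   release?
#' @param interval_fraction fraction of a year the interval spans, in (0, 1].
#' @return survival probability.
#' @export
adult_survival_prob <- function(params, sex = "female",
                                is_first_interval = FALSE,
                                interval_fraction = 1) {
  if (!is.numeric(interval_fraction) || interval_fraction <= 0 ||
      interval_fraction > 1)
    stop("interval_fraction must be in (0, 1]")
  sex <- match_level(sex, SEX_LEVELS, "sex")
  lgt <- qlogis(params$phi_a) + params$beta_sex * (sex == "male") +
    params$delta_trans * is_first_interval
  plogis(lgt)^interval_fraction
}

#' Apparent juvenile survival probability
#'
#' `logistic(logit(phi_j_mean) + eps_year_j\[t\] + beta_dens_j density +
#' gamma_band I\[fledgling-banded\])`.  "Apparent" because permanent
#' emigration is confounded with mortality.  The density covariate is taken
#' as given: pass it on whatever scale the slope was defined on (the fitted
#' model standardizes internally and back-transforms its slope).
#'
#' @param params a [parameter_set()].
#' @param year_index 0-based season index into `eps_year_j`; ignored when no
#'   deviates are stored.
#' @param density density covariate value.
#' @param banding_method `"nestling"` or `"fledgling"`.
#' @return survival probability (fledging to adulthood).
#' @export
juvenile_survival_prob <- function(params, year_index = 0, density = 0,
                                   banding_method = "nestling") {
  if (!all(banding_method %in% c("nestling", "fledgling")))
    stop("unknown banding method: ",
         paste(setdiff(banding_method, c("nestling", "fledgling")),
               collapse = ", "))
  eps <- if (length(params$eps_year_j)) {
    if (any(year_index < 0 | year_index >= length(params$eps_year_j)))
      stop("year_index outside the range of eps_year_j")
    params$eps_year_j[year_index + 1]
  } else 0
  plogis(qlogis(params$phi_j_mean) + eps + params$beta_dens_j * density +
           params$gamma_band * (banding_method == "fledgling"))
}

# Build the per-individual survival matrix and per-occasion resighting
# vector implied by a parameter set, mirroring the fitted model's linear
# predictors.  density_j: per-interval density covariate for juveniles.
build_survival_arrays <- function(ch, params, density_j = NULL) {
  ind <- ch$individuals
  n <- nrow(ind)
  T <- n_occasions(ch)
  nI <- T - 1L
  if (is.null(density_j)) density_j <- numeric(nI)
  frac <- rep(1, nI)
  frac[1] <- ch$first_interval_fraction
  eps_j <- rep(0, nI)
  if (length(params$eps_year_j)) {
    idx <- seq_len(min(nI, length(params$eps_year_j)))
    # season s deviates act on interval s (0-based interval index s)
    take <- idx[idx + 1L <= nI]
    eps_j[take + 1L] <- params$eps_year_j[take]
  }
  eps_p <- rep(0, T)
  if (length(params$eps_year_p))
    eps_p[seq_len(min(T, length(params$eps_year_p)))] <-
      params$eps_year_p[seq_len(min(T, length(params$eps_year_p)))]
  phi <- matrix(0, n, nI)
  juv_int <- ifelse(ind$origin == "wild-born", ind$first_occasion, -1L)
  for (t in seq_len(nI) - 1L) {
    is_juv <- juv_int == t
    lgt <- ifelse(is_juv,
                  qlogis(params$phi_j_mean) + eps_j[t + 1L] +
                    params$beta_dens_j * density_j[t + 1L] +
                    params$gamma_band * (ind$banding_method == "fledgling"),
                  qlogis(params$phi_a) +
                    params$beta_sex * (ind$sex == "male") +
                    params$delta_trans * (ind$origin == "translocated" &
                                            ind$first_occasion == t))
    phi[, t + 1L] <- plogis(lgt)^frac[t + 1L]
  }
  p <- plogis(qlogis(params$p) + eps_p)
  list(phi = phi, p = p)
}

#' Marginalized CJS log-likelihood
#'
#' The exact log-probability of the detection matrix given the parameters,
#' with the latent alive/dead states summed out by the forward recursion and
#' conditioning on first capture.  This is the production likelihood; the
#' state-space formulation survives in [cjs_enumeration_oracle()] for
#' verification.
#'
#' @param history a [capture_history()].
#' @param params a [parameter_set()].
#' @param density_j optional per-interval density covariate for juvenile
#'   survival.
#' @return log-likelihood (`-Inf` for impossible data, e.g. a resighting
#'   when `p = 0` would be approached).
#' @export
cjs_marginal_loglik <- function(history, params, density_j = NULL) {
  a <- build_survival_arrays(history, params, density_j)
  cjs_loglik_cpp(history$detections, history$individuals$first_occasion,
                 a$phi, a$p)
}

#' Brute-force latent-state CJS likelihood (test oracle)
#'
#' Enumerates every alive/dead state sequence after first capture
#' (2^(T-f-1) terms per individual) and sums the state-space model's
#' transition and observation probabilities directly.  Deliberately
#' independent of the forward recursion; limited to 12 occasions.
#'
#' @inheritParams cjs_marginal_loglik
#' @return log-likelihood.
#' @export
cjs_enumeration_oracle <- function(history, params, density_j = NULL) {
  T <- n_occasions(history)
  if (T > 12) stop("enumeration oracle is limited to 12 occasions")
  a <- build_survival_arrays(history, params, density_j)
  det <- history$detections
  first <- history$individuals$first_occasion
  total <- 0
  for (i in seq_len(nrow(det))) {
    f <- first[i]
    m <- T - 1L - f  # occasions after first capture
    lik_i <- 0
    if (m == 0) {
      lik_i <- 1
    } else {
      for (code in 0:(2^m - 1)) {
        states <- c(1L, as.integer(intToBits(code)[seq_len(m)]))  # 1 = alive
        pr <- 1
        for (s in seq_len(m)) {
          occ <- f + s  # 0-based occasion
          from <- states[s]
          to <- states[s + 1]
          trans <- if (from == 1L) {
            if (to == 1L) a$phi[i, occ] else 1 - a$phi[i, occ]
          } else {
            if (to == 1L) 0 else 1
          }
          y <- det[i, occ + 1L]
          emit <- if (to == 1L) {
            if (y == 1L) a$p[occ + 1L] else 1 - a$p[occ + 1L]
          } else {
            if (y == 1L) 0 else 1
          }
          pr <- pr * trans * emit
          if (pr == 0) break
        }
        lik_i <- lik_i + pr
      }
    }
    if (lik_i <= 0) return(-Inf)
    total <- total + log(lik_i)
  }
  total
}
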