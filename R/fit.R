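SCALAR_NAMES <- c("logit_phi_a", "beta_sex", "delta_trans", "logit_phi_j",
                  "beta_dens_j", "gamma_band", "sigma_year_j", "logit_p",
                  "sigma_year_p", "alpha_f", "beta_dens_f", "sigma_female",
                  "sigma_year_f")

#' Fit the integrated population model
#'
#' Samples the joint posterior of the CJS survival model and the Poisson
#' fecundity model.  The two likelihoods share nothing but the priors and,
#' when density dependence on juvenile survival is enabled, the abundance
#' series used as its covariate; fecundity records carry their own observed
#' density covariate.  Sampling is adaptive random-walk
#' Metropolis-within-Gibbs with the likelihood kernels in compiled code;
#' convergence is checked with split-chain R-hat and effective sample size.
#'
#' Density covariates are centered and scaled internally for sampler
#' geometry; the returned draws of `alpha_f`, `beta_dens_f`, `logit_phi_j`
#' and `beta_dens_j` are back-transformed to the raw density scale (the
#' intercepts refer to zero density).
#'
#' Effects whose covariate carries no variation in the data (for example a
#' sex effect when only one sex is present, or a banding-age effect when all
#' birds were banded the same way) are switched off automatically and noted
#' in the result.
#'
#' @param data list with `capture_history`, `fecundity`, `unbanded` (the
#'   output of [simulate_population()] or [read_dataset()]).
#' @param priors a `"prior_set"`; see [uninformative_priors()] and
#'   [informative_priors()].
#' @param config a [model_config()].
#' @param density_juvenile optional per-interval abundance series for the
#'   juvenile density effect; when omitted under `density_on_juvenile`, a
#'   preliminary fit without density effects supplies its posterior-mean
#'   abundance (one-step plug-in).
#' @param on_nonconvergence `"error"` (default) to fail loudly when any
#'   R-hat exceeds 1.1, `"warn"`, or `"none"` (for bulk simulation studies
#'   where individual fits are summarized downstream).
#' @return an object of class `"ipm_fit"`: posterior `draws` (matrix, one
#'   named column per parameter), `chain` ids, `diagnostics` (R-hat and
#'   effective sample size per sampled parameter), the `config`, `priors`
#'   and `data` used, and bookkeeping needed by the derived-quantity
#'   functions.
#' @seealso [derive_lambda()], [carrying_capacity()], [reduce_model()],
#'   [estimate_abundance()], [sequential_analysis()]
#' @export
fit_ipm <- function(data, priors = uninformative_priors(),
                    config = model_config(), density_juvenile = NULL,
                    on_nonconvergence = c("error", "warn", "none")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  validate_dataset(data)
  ch <- data$capture_history
  fec <- data$fecundity
  ind <- ch$individuals
  n <- nrow(ind)
  T <- n_occasions(ch)
  nI <- T - 1L
  notes <- character()

  # one-step plug-in for the juvenile density covariate
  if (config$density_on_juvenile && is.null(density_juvenile)) {
    cfg0 <- config
    cfg0$density_on_juvenile <- FALSE
    cfg0$density_on_fecundity <- FALSE
    cfg0$iterations <- max(2000L, config$iterations %/% 4L)
    cfg0$burn_in <- max(500L, config$burn_in %/% 4L)
    fit0 <- fit_ipm(data, priors, cfg0, on_nonconvergence = "none")
    ab <- estimate_abundance(fit0, n_draws = 200)
    tot <- ab$series[ab$series$sex == "total", ]
    density_juvenile <- tot$mean[match(seq_len(nI) - 1L, tot$occasion)]
    density_juvenile[is.na(density_juvenile)] <- 0
    notes <- c(notes, "juvenile density covariate: plug-in posterior-mean abundance")
  }
  if (is.null(density_juvenile)) density_juvenile <- numeric(nI)

  juvint <- ifelse(ind$origin == "wild-born", ind$first_occasion, -1L)
  # birds first marked at the final occasion contribute no interval
  has_juv <- any(juvint >= 0 & juvint < nI)
  frac <- rep(1, nI)
  frac[1] <- ch$first_interval_fraction

  flags <- c(sex = config$sex_on_adult,
             trans = config$translocation_effect,
             band = config$banding_age_effect,
             densj = config$density_on_juvenile,
             yrej = config$year_re_on_juvenile,
             yrep = config$year_re_on_resighting,
             densf = config$density_on_fecundity,
             femre = config$female_re_on_fecundity,
             yref = config$year_re_on_fecundity)
  disable <- function(flag, why) {
    if (flags[[flag]]) {
      flags[[flag]] <<- FALSE
      notes <<- c(notes, paste0(flag, " effect disabled: ", why))
    }
  }
  if (length(unique(ind$sex[ind$sex != "unknown"])) < 2)
    disable("sex", "fewer than two sexes observed")
  if (!any(ind$origin == "translocated"))
    disable("trans", "no translocated individuals")
  wb <- ind$origin == "wild-born"
  if (!any(wb & ind$banding_method == "fledgling") ||
      !any(wb & ind$banding_method == "nestling"))
    disable("band", "no variation in banding method")
  juv_ints <- sort(unique(juvint[juvint >= 0 & juvint < nI]))
  if (flags[["densj"]] && sd(density_juvenile[juv_ints + 1L]) %in% c(0, NA))
    disable("densj", "no variation in juvenile density covariate")
  if (!has_juv) {
    disable("yrej", "no juveniles")
    disable("densj", "no juveniles")
    disable("band", "no juveniles")
  }
  if (!nrow(fec)) {
    disable("densf", "no fecundity records")
    disable("femre", "no fecundity records")
    disable("yref", "no fecundity records")
  } else {
    if (length(unique(fec$year)) < 2)
      disable("yref", "single breeding season")
    if (sd(fec$density) == 0) disable("densf", "constant density")
  }

  # standardization of density covariates
  std <- function(x, on) {
    if (!on || !length(x)) return(list(z = x * 0, mu = 0, sd = 1))
    mu <- mean(x)
    s <- sd(x)
    if (!is.finite(s) || s == 0) s <- 1
    list(z = (x - mu) / s, mu = mu, sd = s)
  }
  dj <- std(density_juvenile, flags[["densj"]])
  dens_s_j <- numeric(nI)
  if (flags[["densj"]]) dens_s_j <- dj$z

  fem_levels <- unique(fec$female_id)
  yr_levels <- sort(unique(fec$year))
  df <- std(fec$density, flags[["densf"]])
  fdat <- list(k = as.integer(fec$fledglings),
               fem = as.integer(match(fec$female_id, fem_levels) - 1L),
               yr = as.integer(match(fec$year, yr_levels) - 1L),
               dens_s = if (flags[["densf"]]) df$z else numeric(nrow(fec)),
               nfem = length(fem_levels), nyr = length(yr_levels))
  if (!nrow(fec)) fdat$fem <- fdat$yr <- integer(0)

  sdat <- list(det = ch$detections, first = ind$first_occasion,
               male = as.integer(ind$sex == "male"),
               trans = as.integer(ind$origin == "translocated"),
               firstint = ind$first_occasion,
               bandf = as.integer(ind$banding_method == "fledgling"),
               juvint = as.integer(juvint), frac = frac, dens_s = dens_s_j)

  pr <- priors_for_sampler(priors)
  npar <- 13L + nI + T + fdat$nfem + fdat$nyr
  o_ej <- 13L; o_ep <- o_ej + nI; o_ef <- o_ep + T; o_ey <- o_ef + fdat$nfem

  mean_fl <- if (nrow(fec)) mean(fec$fledglings) else 1
  make_init <- function() {
    th <- numeric(npar)
    th[1] <- qlogis(0.7) + rnorm(1, 0, 0.3)
    th[4] <- qlogis(0.3) + rnorm(1, 0, 0.3)
    th[8] <- qlogis(0.8) + rnorm(1, 0, 0.3)
    th[10] <- log(mean_fl + 0.1) + rnorm(1, 0, 0.2)
    for (j in c(7, 9, 12, 13)) th[j] <- runif(1, 0.1, 0.5)  # sigmas
    th
  }

  ctrl_base <- list(flags = flags, has_juveniles = has_juv,
                    ej_active = as.integer(juv_ints),
                    n_iter = config$iterations, n_burn = config$burn_in,
                    thin = config$thin)
  chains <- vector("list", config$chains)
  for (ci in seq_len(config$chains)) {
    set.seed(config$seed + ci - 1L)
    ctrl <- ctrl_base
    ctrl$init <- make_init()
    chains[[ci]] <- ipm_mcmc_cpp(sdat, fdat, pr, ctrl)
  }
  active <- chains[[1]]$active

  nm <- c(SCALAR_NAMES,
          paste0("eps_j_", seq_len(nI) - 1L),
          paste0("eps_p_", seq_len(T) - 1L),
          if (fdat$nfem) paste0("eps_fem_", fem_levels),
          if (fdat$nyr) paste0("eps_fy_", yr_levels))
  keep_cols <- active | seq_len(npar) <= 13L  # all scalars + active eps
  draws_list <- lapply(chains, function(cc) {
    m <- cc$draws
    colnames(m) <- nm
    # back-transform to the raw density scale
    if (flags[["densf"]]) {
      m[, "alpha_f"] <- m[, "alpha_f"] - m[, "beta_dens_f"] * df$mu / df$sd
      m[, "beta_dens_f"] <- m[, "beta_dens_f"] / df$sd
    }
    if (flags[["densj"]]) {
      m[, "logit_phi_j"] <- m[, "logit_phi_j"] -
        m[, "beta_dens_j"] * dj$mu / dj$sd
      m[, "beta_dens_j"] <- m[, "beta_dens_j"] / dj$sd
    }
    m[, keep_cols, drop = FALSE]
  })
  draws <- do.call(rbind, draws_list)
  chain_id <- rep(seq_len(config$chains), vapply(draws_list, nrow, 0L))

  diag_cols <- nm[active]
  mcl <- coda::mcmc.list(lapply(draws_list, function(m)
    coda::mcmc(m[, diag_cols, drop = FALSE])))
  rhat <- rep(NA_real_, length(diag_cols))
  if (config$chains >= 2) {
    rhat <- tryCatch(
      coda::gelman.diag(mcl, autoburnin = FALSE,
                        multivariate = FALSE)$psrf[, 1],
      error = function(e) rep(NA_real_, length(diag_cols)))
  }
  ess <- tryCatch(coda::effectiveSize(mcl),
                  error = function(e) rep(NA_real_, length(diag_cols)))
  diagnostics <- data.frame(parameter = diag_cols, rhat = as.numeric(rhat),
                            ess = as.numeric(ess),
                            stringsAsFactors = FALSE)
  bad <- diagnostics$parameter[!is.na(diagnostics$rhat) &
                                 diagnostics$rhat > 1.1]
  if (length(bad)) {
    msg <- paste0("MCMC has not converged (R-hat > 1.1) for: ",
                  paste(bad, collapse = ", "))
    if (on_nonconvergence == "error") stop(msg, call. = FALSE)
    if (on_nonconvergence == "warn") warning(msg, call. = FALSE)
  }

  structure(list(draws = draws, chain = chain_id, diagnostics = diagnostics,
                 config = config, priors = priors, data = data,
                 flags = flags, notes = notes,
                 density_info = list(juvenile = density_juvenile,
                                     mu_j = dj$mu, sd_j = dj$sd,
                                     mu_f = df$mu, sd_f = df$sd),
                 fem_levels = fem_levels, yr_levels = yr_levels,
                 n_years_used = nI - sum(frac < 1),
                 seed = config$seed),
            class = "ipm_fit")
}

#' @export
print.ipm_fit <- function(x, ...) {
  cat("<ipm_fit> ", nrow(x$draws), " draws x ", ncol(x$draws),
      " parameters (", max(x$chain), " chains)\n", sep = "")
  s <- posterior_summary(x, c("logit_phi_a", "logit_phi_j", "logit_p",
                              "alpha_f"))
  cat(sprintf("  adult survival  %.3f (%.3f-%.3f)\n",
              plogis(s["logit_phi_a", 1]), plogis(s["logit_phi_a", 2]),
              plogis(s["logit_phi_a", 3])))
  cat(sprintf("  juv. survival   %.3f (%.3f-%.3f)\n",
              plogis(s["logit_phi_j", 1]), plogis(s["logit_phi_j", 2]),
              plogis(s["logit_phi_j", 3])))
  cat(sprintf("  resighting      %.3f (%.3f-%.3f)\n",
              plogis(s["logit_p", 1]), plogis(s["logit_p", 2]),
              plogis(s["logit_p", 3])))
  cat(sprintf("  mean fecundity  %.2f (%.2f-%.2f)  [at zero density]\n",
              exp(s["alpha_f", 1]), exp(s["alpha_f", 2]),
              exp(s["alpha_f", 3])))
  mx <- suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))
  if (is.finite(mx)) cat(sprintf("  max R-hat %.3f\n", mx))
  invisible(x)
}

# median and central 95% interval of selected (possibly transformed) columns
posterior_summary <- function(fit, cols) {
  t(vapply(cols, function(cn) {
    v <- fit$draws[, cn]
    c(mean(v), quantile(v, c(0.025, 0.975)))
  }, numeric(3)))
}

#' Rebuild a parameter set from one posterior draw
#'
#' Maps row `i` of the posterior draw matrix back onto a [parameter_set()],
#' including the random-effect deviates, so that the likelihood and
#' abundance machinery can be driven by individual draws.
#'
#' @param fit an `"ipm_fit"`.
#' @param i draw index.
#' @return a [parameter_set()].
#' @export
draw_parameter_set <- function(fit, i) {
  d <- fit$draws[i, ]
  T <- n_occasions(fit$data$capture_history)
  nI <- T - 1L
  get0v <- function(nms) ifelse(nms %in% names(d), d[nms], 0)
  eps_j <- unname(get0v(paste0("eps_j_", seq_len(max(nI - 1L, 0)))))
  eps_p <- unname(get0v(paste0("eps_p_", seq_len(T) - 1L)))
  eps_fem <- if (length(fit$fem_levels))
    setNames(unname(get0v(paste0("eps_fem_", fit$fem_levels))),
             fit$fem_levels) else numeric()
  eps_fy <- if (length(fit$yr_levels))
    setNames(unname(get0v(paste0("eps_fy_", fit$yr_levels))),
             as.character(fit$yr_levels)) else numeric()
  clamp <- function(x) pmin(pmax(x, 1e-12), 1 - 1e-12)
  parameter_set(
    phi_a = clamp(plogis(d[["logit_phi_a"]])),
    phi_j_mean = clamp(plogis(d[["logit_phi_j"]])),
    sigma_year_j = d[["sigma_year_j"]], eps_year_j = eps_j,
    beta_dens_j = d[["beta_dens_j"]], gamma_band = d[["gamma_band"]],
    beta_sex = d[["beta_sex"]], delta_trans = d[["delta_trans"]],
    p = clamp(plogis(d[["logit_p"]])), sigma_year_p = d[["sigma_year_p"]],
    eps_year_p = eps_p,
    alpha_f = d[["alpha_f"]], beta_dens_f = d[["beta_dens_f"]],
    sigma_female = d[["sigma_female"]], eps_female = eps_fem,
    sigma_year_f = d[["sigma_year_f"]], eps_year_f = eps_fy)
}
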