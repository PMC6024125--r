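SEX_LEVELS <- c("male", "female", "unknown")
ORIGIN_LEVELS <- c("translocated", "wild-born")
BANDING_LEVELS <- c("nestling", "fledgling", "not-applicable")

#' Individual registry
#'
#' Builds and validates the per-individual covariate table used by the
#' survival model: identity, sex, origin (translocated founder vs wild-born
#' recruit), banding method (nestling vs fledgling, relevant to wild-born
#' birds only) and the 0-based survey occasion of first capture or release.
#'
#' @param id character vector of unique identifiers.
#' @param sex one of `"male"`, `"female"`, `"unknown"` per individual
#'   (wild-born birds may be unsexed until adulthood).
#' @param origin `"translocated"` or `"wild-born"`.
#' @param banding_method `"nestling"` or `"fledgling"` for wild-born birds;
#'   translocated birds are flagged `"not-applicable"` regardless of input.
#' @param first_occasion integer, 0-based index of the occasion at which the
#'   individual enters the marked population (release or banding).
#' @return a `data.frame` with one row per individual.
#' @export
individuals <- function(id, sex, origin, banding_method, first_occasion) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicated individual ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  sex <- match_level(sex, SEX_LEVELS, "sex")
  origin <- match_level(origin, ORIGIN_LEVELS, "origin")
  banding_method <- match_level(banding_method, BANDING_LEVELS,
                                "banding_method")
  banding_method[origin == "translocated"] <- "not-applicable"
  first_occasion <- as.integer(first_occasion)
  if (anyNA(first_occasion) || any(first_occasion < 0))
    stop("first_occasion must be a non-negative integer")
  data.frame(id = id, sex = sex, origin = origin,
             banding_method = banding_method,
             first_occasion = first_occasion,
             stringsAsFactors = FALSE)
}

match_level <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !x %in% levels
  if (any(bad))
    stop("invalid ", what, " code: ",
         paste(unique(x[bad]), collapse = ", "),
         " (allowed: ", paste(levels, collapse = ", "), ")")
  x
}

#' Capture/resighting history
#'
#' The survival-model input: a binary detection matrix (individual x annual
#' survey occasion) together with the individual registry and occasion
#' labels.  Detection is fixed to 1 at each individual's first occasion (the
#' CJS likelihood conditions on first capture) and must be 0 before it.
#'
#' @param detections binary matrix, one row per individual, one column per
#'   occasion.
#' @param individuals registry built by [individuals()].
#' @param occasions optional `data.frame` with columns `occasion` (0-based)
#'   and `label`; defaults to plain integer labels.
#' @param first_interval_fraction fraction of a year covered by the first
#'   interval (release to first annual survey); 0.5 for a mid-year release
#'   followed by a survey six months later, 1 for ordinary annual data.
#'   Annual survival is raised to this power over that interval.
#' @return an object of class `"capture_history"`.
#' @export
capture_history <- function(detections, individuals, occasions = NULL,
                            first_interval_fraction = 1) {
  detections <- as.matrix(detections)
  storage.mode(detections) <- "integer"
  n <- nrow(detections)
  T <- ncol(detections)
  if (n != nrow(individuals))
    stop("detections has ", n, " rows but registry has ", nrow(individuals))
  if (!all(detections %in% c(0L, 1L)))
    stop("detection matrix entries must be 0 or 1")
  if (any(individuals$first_occasion > T - 1))
    stop("first_occasion outside the study's occasion range")
  if (!is.numeric(first_interval_fraction) ||
      first_interval_fraction <= 0 || first_interval_fraction > 1)
    stop("first_interval_fraction must be in (0, 1]")
  for (i in seq_len(n)) {
    f <- individuals$first_occasion[i]
    if (detections[i, f + 1L] != 1L)
      stop("individual ", individuals$id[i],
           ": no detection at its first occasion ", f)
    if (f > 0 && any(detections[i, seq_len(f)] == 1L))
      stop("individual ", individuals$id[i],
           ": detection before first occasion ", f)
  }
  if (is.null(occasions))
    occasions <- data.frame(occasion = 0:(T - 1),
                            label = as.character(0:(T - 1)),
                            stringsAsFactors = FALSE)
  if (nrow(occasions) != T)
    stop("occasions table must have one row per detection column")
  rownames(detections) <- individuals$id
  structure(list(detections = detections, individuals = individuals,
                 occasions = occasions,
                 first_interval_fraction = first_interval_fraction),
            class = "capture_history")
}

#' @export
print.capture_history <- function(x, ...) {
  cat("<capture_history> ", nrow(x$detections), " individuals x ",
      ncol(x$detections), " occasions\n", sep = "")
  tab <- table(x$individuals$origin)
  cat("  origin: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  first interval fraction: ", x$first_interval_fraction, "\n", sep = "")
  invisible(x)
}

n_occasions <- function(ch) ncol(ch$detections)

#' Per-female annual fledgling counts
#'
#' One row per monitored female per breeding season: the number of young
#' fledged and the breeding population size (density covariate) at the start
#' of that season.  `year` is the 0-based survey occasion at which the season
#' starts.
#'
#' @param female_id,year,fledglings,density vectors of equal length.
#' @return a `data.frame` of class `"fecundity_records"`.
#' @export
fecundity_records <- function(female_id = character(), year = integer(),
                              fledglings = integer(), density = numeric()) {
  df <- data.frame(female_id = as.character(female_id),
                   year = as.integer(year),
                   fledglings = as.integer(fledglings),
                   density = as.numeric(density),
                   stringsAsFactors = FALSE)
  if (any(df$fledglings < 0)) stop("fledglings must be non-negative")
  if (nrow(df) && any(!is.finite(df$density) | df$density <= 0))
    stop("density must be positive wherever a record exists")
  class(df) <- c("fecundity_records", "data.frame")
  df
}

#' Counts of unbanded birds per survey
#'
#' @param occasion,sex,count vectors of equal length; `sex` may be
#'   `"unknown"` for unsexed birds.
#' @return a `data.frame` of class `"unbanded_counts"`.
#' @export
unbanded_counts <- function(occasion = integer(), sex = character(),
                            count = integer()) {
  df <- data.frame(occasion = as.integer(occasion),
                   sex = match_level(sex, SEX_LEVELS, "sex"),
                   count = as.integer(count), stringsAsFactors = FALSE)
  if (any(df$count < 0)) stop("count must be non-negative")
  class(df) <- c("unbanded_counts", "data.frame")
  df
}

#' Cross-validate a dataset
#'
#' Checks that every fecundity record refers to a female in the capture
#' history registry and that record years fall inside the occasion range.
#'
#' @param data list with elements `capture_history`, `fecundity`, `unbanded`.
#' @return `data`, invisibly, after validation.
#' @export
validate_dataset <- function(data) {
  ch <- data$capture_history
  fec <- data$fecundity
  if (nrow(fec)) {
    missing <- setdiff(fec$female_id, ch$individuals$id)
    if (length(missing))
      stop("fecundity records refer to unknown females: ",
           paste(missing, collapse = ", "))
    not_female <- ch$individuals$id[ch$individuals$sex == "male"]
    bad <- intersect(fec$female_id, not_female)
    if (length(bad))
      stop("fecundity records for male individuals: ",
           paste(bad, collapse = ", "))
    if (any(fec$year < 0 | fec$year > n_occasions(ch) - 1))
      stop("fecundity record year outside occasion range")
  }
  if (nrow(data$unbanded) &&
      any(data$unbanded$occasion > n_occasions(ch) - 1))
    stop("unbanded count occasion outside occasion range")
  invisible(data)
}

#' Demographic parameter set
#'
#' One realization of every demographic parameter used by the survival and
#' fecundity models.  Survival and resighting probabilities are stored on the
#' probability scale; regression effects and random-effect deviates live on
#' the link (logit or log) scale where they enter the linear predictors.
#'
#' @param phi_a annual adult survival probability.
#' @param phi_j_mean mean apparent juvenile survival (fledging to adulthood),
#'   probability scale; year deviates act on its logit.
#' @param sigma_year_j SD of the random year effect on logit juvenile
#'   survival.
#' @param eps_year_j named or plain numeric vector of per-year deviates
#'   (logit scale).
#' @param beta_dens_j density slope on logit juvenile survival.
#' @param gamma_band effect (logit scale) of being banded as a fledgling
#'   rather than a nestling.
#' @param beta_sex effect (logit scale) of being male on adult survival.
#' @param delta_trans translocation effect (logit scale) on survival over a
#'   founder's first interval.
#' @param p resighting probability per survey.
#' @param sigma_year_p SD of the random year effect on logit resighting.
#' @param eps_year_p per-occasion deviates (logit scale).
#' @param alpha_f log mean fecundity at zero density.
#' @param beta_dens_f density slope on log fecundity.
#' @param sigma_female SD of the female random effect on log fecundity.
#' @param eps_female named numeric vector of per-female deviates (log scale).
#' @param sigma_year_f SD of the year random effect on log fecundity.
#' @param eps_year_f per-year deviates (log scale).
#' @return an object of class `"parameter_set"`.
#' @export
parameter_set <- function(phi_a = 0.78, phi_j_mean = 0.25,
                          sigma_year_j = 0, eps_year_j = numeric(),
                          beta_dens_j = 0, gamma_band = 0,
                          beta_sex = 0, delta_trans = 0,
                          p = 0.9, sigma_year_p = 0, eps_year_p = numeric(),
                          alpha_f = log(3.8), beta_dens_f = 0,
                          sigma_female = 0, eps_female = numeric(),
                          sigma_year_f = 0, eps_year_f = numeric()) {
  for (pr in list(phi_a = phi_a, phi_j_mean = phi_j_mean, p = p)) {
    if (!is.numeric(pr) || pr <= 0 || pr >= 1)
      stop("probabilities must lie strictly in (0, 1)")
  }
  for (s in list(sigma_year_j, sigma_year_p, sigma_female, sigma_year_f))
    if (s < 0) stop("random-effect SDs must be >= 0")
  structure(list(phi_a = phi_a, phi_j_mean = phi_j_mean,
                 sigma_year_j = sigma_year_j, eps_year_j = eps_year_j,
                 beta_dens_j = beta_dens_j, gamma_band = gamma_band,
                 beta_sex = beta_sex, delta_trans = delta_trans,
                 p = p, sigma_year_p = sigma_year_p, eps_year_p = eps_year_p,
                 alpha_f = alpha_f, beta_dens_f = beta_dens_f,
                 sigma_female = sigma_female, eps_female = eps_female,
                 sigma_year_f = sigma_year_f, eps_year_f = eps_year_f),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  adult survival %.3f  juvenile survival %.3f  resighting %.3f\n",
              x$phi_a, x$phi_j_mean, x$p))
  cat(sprintf("  mean fecundity exp(alpha_f) = %.3f  density slope %.4g\n",
              exp(x$alpha_f), x$beta_dens_f))
  invisible(x)
}

#' Model configuration
#'
#' Flags for every optional effect, the prior mode and MCMC settings.  The
#' defaults correspond to the full model: all fixed effects, density effects
#' and random effects switched on.  Intercepts (adult survival, juvenile
#' survival, resighting, fecundity) are always present.
#'
#' @param density_on_fecundity,year_re_on_fecundity,female_re_on_fecundity
#'   fecundity-side switches.
#' @param density_on_juvenile,year_re_on_juvenile survival-side switches for
#'   juveniles.
#' @param sex_on_adult,translocation_effect,banding_age_effect adult/juvenile
#'   fixed effects.
#' @param year_re_on_resighting random year effect on logit resighting.
#' @param prior_mode `"uninformative"` or `"informative"`.
#' @param iterations,burn_in,chains,thin,seed MCMC settings.  The historical
#'   defaults (50,000 iterations, 5,000 burn-in) are generous for this
#'   sampler; effective sample size, not iteration count, is the convergence
#'   contract.
#' @param re_drop_threshold link-scale SD below which the posterior 25th
#'   percentile must fall for [reduce_model()] to drop a random effect.
#' @return an object of class `"model_config"` (a list).
#' @export
model_config <- function(density_on_fecundity = TRUE,
                         year_re_on_fecundity = TRUE,
                         female_re_on_fecundity = TRUE,
                         density_on_juvenile = TRUE,
                         year_re_on_juvenile = TRUE,
                         sex_on_adult = TRUE,
                         translocation_effect = TRUE,
                         banding_age_effect = TRUE,
                         year_re_on_resighting = TRUE,
                         prior_mode = c("uninformative", "informative"),
                         iterations = 50000, burn_in = 5000, chains = 4,
                         thin = 10, seed = 20070301,
                         re_drop_threshold = 0.05) {
  prior_mode <- match.arg(prior_mode)
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  structure(list(density_on_fecundity = density_on_fecundity,
                 year_re_on_fecundity = year_re_on_fecundity,
                 female_re_on_fecundity = female_re_on_fecundity,
                 density_on_juvenile = density_on_juvenile,
                 year_re_on_juvenile = year_re_on_juvenile,
                 sex_on_adult = sex_on_adult,
                 translocation_effect = translocation_effect,
                 banding_age_effect = banding_age_effect,
                 year_re_on_resighting = year_re_on_resighting,
                 prior_mode = prior_mode,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 chains = as.integer(chains), thin = as.integer(thin),
                 seed = as.integer(seed),
                 re_drop_threshold = re_drop_threshold),
            class = "model_config")
}
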