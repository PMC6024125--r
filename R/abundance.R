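#' Posterior number of banded birds alive per occasion
#'
#' For each (thinned) posterior draw, the forward-backward algorithm gives
#' every individual's probability of being alive at every occasion given its
#' detection history; summing those marginal probabilities over individuals
#' yields the expected number of marked birds alive, by sex.  This matches
#' the marginalized likelihood and has lower Monte-Carlo variance than
#' sampling latent states.  An individual resighted at an occasion
#' contributes exactly 1 there, so every draw's count is bounded below by
#' the number of birds actually seen at the survey.
#'
#' One census subtlety: wild-born chicks are banded mid-season, after the
#' survey that indexes their entry into the capture history, so they are not
#' part of that occasion's pre-breeding census and are counted only from the
#' following survey onwards.  Translocated founders are present from their
#' release occasion.
#'
#' @param fit an `"ipm_fit"`, or `NULL` to use fixed parameters.
#' @param history a [capture_history()]; defaults to the one inside `fit`.
#' @param params a [parameter_set()] used when `fit` is `NULL` (a single
#'   "draw").
#' @param n_draws number of evenly spaced posterior draws to evaluate.
#' @return an object of class `"abundance_component"`: a list of draw x
#'   occasion matrices, one per sex group plus `total`.
#' @export
banded_alive <- function(fit = NULL, history = NULL, params = NULL,
                         n_draws = 500) {
  if (is.null(history)) history <- fit$data$capture_history
  T <- n_occasions(history)
  sexes <- history$individuals$sex
  groups <- split(seq_along(sexes), factor(sexes, levels = SEX_LEVELS))
  dens_j <- if (!is.null(fit)) fit$density_info$juvenile else NULL
  wild <- which(history$individuals$origin == "wild-born")
  entry <- history$individuals$first_occasion
  one_draw <- function(par) {
    a <- build_survival_arrays(history, par, dens_j)
    m <- cjs_alive_marginals_cpp(history$detections,
                                 history$individuals$first_occasion,
                                 a$phi, a$p)
    # wild-born birds fledge after the survey indexing their entry: not in
    # that occasion's census
    if (length(wild)) m[cbind(wild, entry[wild] + 1L)] <- 0
    vapply(groups, function(ix) colSums(m[ix, , drop = FALSE]), numeric(T))
  }
  if (is.null(fit)) {
    stopifnot(!is.null(params))
    per <- list(one_draw(params))
  } else {
    idx <- unique(round(seq(1, nrow(fit$draws), length.out =
                              min(n_draws, nrow(fit$draws)))))
    per <- lapply(idx, function(i) one_draw(draw_parameter_set(fit, i)))
  }
  out <- lapply(SEX_LEVELS, function(s)
    do.call(rbind, lapply(per, function(m) m[, s])))
  names(out) <- SEX_LEVELS
  out$total <- out$male + out$female + out$unknown
  structure(out, class = "abundance_component", occasions = 0:(T - 1))
}

#' Birds seen at each survey (census sense)
#'
#' Per-occasion count of marked individuals detected, excluding wild-born
#' birds at their own entry occasion (the banding of a chick mid-season is
#' not a sighting at the preceding survey).  Abundance estimates are bounded
#' below by these counts.
#'
#' @param history a [capture_history()].
#' @return integer vector, one count per occasion.
#' @export
census_detections <- function(history) {
  det <- history$detections
  wild <- which(history$individuals$origin == "wild-born")
  if (length(wild))
    det[cbind(wild, history$individuals$first_occasion[wild] + 1L)] <- 0L
  colSums(det)
}

#' Detection-corrected number of unbanded birds
#'
#' Horvitz-Thompson: the count of unbanded birds seen at a survey divided by
#' the resighting probability, per posterior draw, under the assumption that
#' detection is equal for banded and unbanded birds.  Draws with p = 0 are
#' excluded with a warning.
#'
#' @param counts an [unbanded_counts()] table.
#' @param p_draws resighting probability per draw: a vector (constant over
#'   occasions within a draw) or a draw x occasion matrix.
#' @param n_occasions number of survey occasions in the study.
#' @return an `"abundance_component"` with one draw x occasion matrix per
#'   sex group (`unknown` holds unsexed birds) plus `total`.
#' @export
unbanded_estimate <- function(counts, p_draws, n_occasions) {
  if (nrow(counts) && any(counts$occasion > n_occasions - 1L))
    stop("unbanded count occasion outside the study's occasion range")
  if (is.vector(p_draws)) p_draws <- matrix(p_draws, length(p_draws),
                                            n_occasions)
  bad <- p_draws == 0
  if (any(bad)) {
    warning("excluding ", sum(rowSums(bad) > 0),
            " draws with p = 0 from the unbanded estimate")
    keep <- rowSums(bad) == 0
    p_draws <- p_draws[keep, , drop = FALSE]
  }
  nd <- nrow(p_draws)
  base <- matrix(0, nd, n_occasions)
  out <- list(male = base, female = base, unknown = base)
  for (r in seq_len(nrow(counts))) {
    occ <- counts$occasion[r] + 1L
    out[[counts$sex[r]]][, occ] <- out[[counts$sex[r]]][, occ] +
      counts$count[r] / p_draws[, occ]
  }
  out$total <- out$male + out$female + out$unknown
  structure(out, class = "abundance_component",
            occasions = 0:(n_occasions - 1))
}

#' Total abundance: banded plus unbanded
#'
#' Elementwise (per-draw, per-occasion) sum of the banded-alive and
#' detection-corrected unbanded components.  Unbanded birds of unknown sex
#' are split between males and females by the banded population's posterior
#' sex ratio at that occasion and draw, the minimal-assumption allocation;
#' the combined total is unaffected by the split.  Draw counts must match:
#' build both components from the same fit with the same `n_draws`.
#'
#' @param banded,unbanded `"abundance_component"` objects on the same
#'   occasions (unbanded may be `NULL`).
#' @return an object of class `"abundance_series"`: a summary `data.frame`
#'   (occasion, sex, mean, lower95, upper95) with the per-draw arrays kept
#'   in `attr(, "draws")`.
#' @export
total_abundance <- function(banded, unbanded = NULL) {
  occ <- attr(banded, "occasions")
  if (!is.null(unbanded)) {
    if (!identical(occ, attr(unbanded, "occasions")))
      stop("banded and unbanded components cover different occasions")
    if (nrow(unbanded$total) != nrow(banded$total))
      stop("banded and unbanded components have different draw counts")
  }
  comp <- list()
  for (s in c("male", "female", "unknown")) {
    comp[[s]] <- banded[[s]]
    if (!is.null(unbanded)) comp[[s]] <- comp[[s]] + unbanded[[s]]
  }
  if (!is.null(unbanded) && any(unbanded$unknown > 0)) {
    mf <- banded$male + banded$female
    ratio <- ifelse(mf > 0, banded$male / mf, 0.5)
    comp$male <- banded$male + unbanded$male + ratio * unbanded$unknown
    comp$female <- banded$female + unbanded$female +
      (1 - ratio) * unbanded$unknown
    comp$unknown <- banded$unknown
  }
  comp$total <- comp$male + comp$female + comp$unknown
  summ <- do.call(rbind, lapply(names(comp), function(s) {
    m <- comp[[s]]
    data.frame(occasion = occ, sex = s, mean = colMeans(m),
               lower95 = apply(m, 2, quantile, 0.025),
               upper95 = apply(m, 2, quantile, 0.975),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(series = summ), draws = comp, class = "abundance_series")
}

#' @export
print.abundance_series <- function(x, ...) {
  tot <- x$series[x$series$sex == "total", ]
  cat("<abundance_series>\n")
  print(tot, row.names = FALSE, digits = 3)
  invisible(x)
}

#' One-call abundance estimate from a fitted model
#'
#' Convenience wrapper: banded-alive component from the fit, unbanded
#' component from the stored counts using the same draws' resighting
#' probabilities, combined with [total_abundance()].
#'
#' @param fit an `"ipm_fit"`.
#' @param n_draws posterior draws to evaluate.
#' @return an `"abundance_series"`.
#' @export
estimate_abundance <- function(fit, n_draws = 500) {
  ch <- fit$data$capture_history
  T <- n_occasions(ch)
  b <- banded_alive(fit, n_draws = n_draws)
  u <- NULL
  if (nrow(fit$data$unbanded)) {
    idx <- unique(round(seq(1, nrow(fit$draws),
                            length.out = min(n_draws, nrow(fit$draws)))))
    epn <- paste0("eps_p_", seq_len(T) - 1L)
    lp <- matrix(fit$draws[idx, "logit_p"], length(idx), T)
    have <- which(epn %in% colnames(fit$draws))
    if (length(have))
      lp[, have] <- lp[, have] +
        as.matrix(fit$draws[idx, epn[have], drop = FALSE])
    u <- unbanded_estimate(fit$data$unbanded, plogis(lp), T)
  }
  total_abundance(b, u)
}
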