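## Nest survival model: interval Bernoulli(phi^l) likelihood with
## logit-linear daily survival (dispersal x previous-fate interaction),
## hierarchical year intercepts, individual random effects, and the shared
## missing-previous-fate submodel.

#' Survival model parameter vector
#'
#' Container for every parameter of the nest survival model:
#' \describe{
#'   \item{delta}{mean daily nest survival across years on the logit scale,
#'     for previously successful individuals}
#'   \item{gamma_d}{dispersal distance effect, per meter (logit scale)}
#'   \item{gamma_f}{previous nest fate effect (logit scale)}
#'   \item{gamma_dxf}{dispersal x previous fate interaction, per meter}
#'   \item{sigma_yr, sigma_ind}{among-year / among-individual SDs on the
#'     logit scale}
#'   \item{pi_yr}{named vector of year intercepts pi_j (logit scale);
#'     years not listed default to delta}
#'   \item{eps_ind}{named vector of individual effects}
#' }
#'
#' @param delta,gamma_d,gamma_f,gamma_dxf Scalars (see above).
#' @param sigma_yr,sigma_ind Non-negative scalars.
#' @param pi_yr,eps_ind Named numeric vectors.
#' @return An object of class \code{survival_params}.
#' @export
survival_params <- function(delta = 0, gamma_d = 0, gamma_f = 0,
                            gamma_dxf = 0, sigma_yr = 0, sigma_ind = 0,
                            pi_yr = numeric(0), eps_ind = numeric(0)) {
  if (sigma_yr < 0 || sigma_ind < 0)
    stop("standard deviations must be non-negative")
  structure(list(delta = delta, gamma_d = gamma_d, gamma_f = gamma_f,
                 gamma_dxf = gamma_dxf, sigma_yr = sigma_yr,
                 sigma_ind = sigma_ind, pi_yr = pi_yr, eps_ind = eps_ind),
            class = "survival_params")
}

#' Daily nest survival probability
#'
#' Inverse logit of pi_j + gamma_d d + gamma_f f + gamma_dxf d f + eps_ind,
#' where d is dispersal distance in meters and f the resolved previous fate
#' (0/1). Year intercepts absent from \code{params$pi_yr} default to
#' \code{delta}; individuals absent from \code{params$eps_ind} contribute 0.
#'
#' @param d Dispersal distance in meters (vectorized).
#' @param f Previous fate, 0 or 1 (vectorized).
#' @param params A [survival_params()] object.
#' @param year,individual_id Optional vectors selecting year intercepts and
#'   individual effects.
#' @return Daily survival probability in (0, 1).
#' @export
daily_survival <- function(d, f, params, year = NULL, individual_id = NULL) {
  if (any(d < 0)) stop("dispersal distance must be non-negative")
  if (anyNA(f)) stop("previous fate must be resolved")
  pi_j <- if (is.null(year)) rep(params$delta, length(d)) else {
    p <- unname(params$pi_yr[as.character(year)])
    p[is.na(p)] <- params$delta
    p
  }
  eps <- if (is.null(individual_id)) 0 else .re_lookup(params$eps_ind, individual_id)
  lp <- pi_j + params$gamma_d * d + params$gamma_f * f +
    params$gamma_dxf * d * f + eps
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  stats::plogis(lp)
}

## log(1 - exp(x)) for x <= 0, numerically stable.
.log1mexp <- function(x) {
  out <- numeric(length(x))
  hi <- x > -0.6931472  # -log(2)
  out[hi] <- log(-expm1(x[hi]))
  out[!hi] <- log1p(-exp(x[!hi]))
  out
}

## Per-interval log likelihood given per-interval daily survival phi.
.interval_ll <- function(phi, l, y) {
  lphi <- log(phi)
  ifelse(y == 1, l * lphi, .log1mexp(l * lphi))
}

#' Nest survival log likelihood
#'
#' Exposure-interval likelihood: each interval of length l with outcome y
#' contributes y l log(phi) + (1 - y) log(1 - phi^l), with phi the nest's
#' daily survival probability. The failure branch is computed via
#' log1p(-exp(l log phi)) to avoid cancellation as phi approaches 1.
#'
#' @param intervals Data frame of exposure intervals (see
#'   [build_exposure_intervals()]) with columns \code{length_days},
#'   \code{outcome}, \code{nest_id}, and per-nest covariates joined via
#'   \code{pairs} or already present as columns \code{dispersal_m},
#'   \code{prev_fate}, \code{year}, \code{individual_id}.
#' @param params A [survival_params()] object.
#' @param fates Optional 0/1 vector (one per interval) overriding
#'   \code{intervals$prev_fate}.
#' @return Scalar log likelihood.
#' @export
survival_loglik <- function(intervals, params, fates = NULL) {
  f <- if (is.null(fates)) intervals$prev_fate else fates
  phi <- daily_survival(intervals$dispersal_m, f, params,
                        year = intervals$year,
                        individual_id = intervals$individual_id)
  ll <- .interval_ll(phi, intervals$length_days, intervals$outcome)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll))
    stop("data/parameter conflict (e.g. phi = 1 with a failed interval) at interval(s) ",
         paste(bad, collapse = ", "))
  }
  sum(ll)
}

#' Nest survival over the full 28-day exposure period
#'
#' Raises daily survival probability to the power 28, the average exposure
#' period assuming a 24-day incubation and a 4-day laying period for a
#' 5-egg clutch.
#'
#' @param phi Daily survival probability in [0, 1] (vectorized).
#' @return phi^28.
#' @export
nest_survival_28 <- function(phi) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  phi^28
}

#' Failure probability for nests with unknown previous fate (survival model)
#'
#' The survival model estimates missing previous fates with the same
#' submodel as the fidelity model; this delegates to [missing_fate_prob()]
#' so both models share one numerical contract.
#'
#' @inheritParams missing_fate_prob
#' @return Failure probability in [0, 1).
#' @export
resolve_missing_fates_survival <- function(last_check_age, phi) {
  missing_fate_prob(last_check_age, phi)
}

#' Vague prior specification for the survival model
#'
#' Defaults: logistic(0, 1) on delta (uniform on the probability scale),
#' normal(0, sd 10) on the regression coefficients, uniform(0, 3) on the
#' SDs.
#'
#' @inheritParams fidelity_prior_spec
#' @export
survival_prior_spec <- function(coef_sd = 10, sd_upper = 3) {
  list(coef_sd = coef_sd, sd_upper = sd_upper)
}
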