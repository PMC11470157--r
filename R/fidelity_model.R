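## Nest-site fidelity model: location-scale t likelihood for log dispersal
## distance with previous-fate, flood and spring-timing effects, crossed
## individual/year random effects, and a Bernoulli missing-previous-fate
## submodel with informative beta priors on daily nest survival.

#' Fidelity model parameter vector
#'
#' Container for every parameter of the nest-site fidelity model:
#' \describe{
#'   \item{mu}{among-year mean log dispersal distance (log meters)}
#'   \item{beta_f}{previous nest fate effect (log scale; fate coded 0 =
#'     success, 1 = fail)}
#'   \item{beta_fxw}{previous fate x flood interaction (log scale)}
#'   \item{eta_s}{spring-timing effect per day of the early-late index}
#'   \item{eta_w}{previous-year flood effect (log scale)}
#'   \item{sigma_ind, sigma_yr}{among-individual / among-year SDs of the
#'     random effects (log scale)}
#'   \item{sigma_resid}{length-2 residual t scale by previous fate
#'     (success, fail)}
#'   \item{kappa}{length-2 t degrees of freedom by previous fate}
#'   \item{eps_ind, eps_yr}{random effect vectors (may be empty for purely
#'     algebraic uses)}
#' }
#'
#' @param mu,beta_f,beta_fxw,eta_s,eta_w Scalars (see above).
#' @param sigma_ind,sigma_yr Non-negative scalars.
#' @param sigma_resid,kappa Length-2 positive vectors indexed by previous
#'   fate + 1.
#' @param eps_ind,eps_yr Named numeric vectors of individual / year effects.
#' @return An object of class \code{fidelity_params}.
#' @export
fidelity_params <- function(mu = 0, beta_f = 0, beta_fxw = 0, eta_s = 0,
                            eta_w = 0, sigma_ind = 0, sigma_yr = 0,
                            sigma_resid = c(1, 1), kappa = c(30, 30),
                            eps_ind = numeric(0), eps_yr = numeric(0)) {
  sigma_resid <- rep_len(as.numeric(sigma_resid), 2L)
  kappa <- rep_len(as.numeric(kappa), 2L)
  if (any(sigma_resid < 0) || sigma_ind < 0 || sigma_yr < 0)
    stop("standard deviations must be non-negative")
  if (any(kappa <= 0)) stop("degrees of freedom must be positive")
  structure(list(mu = mu, beta_f = beta_f, beta_fxw = beta_fxw,
                 eta_s = eta_s, eta_w = eta_w, sigma_ind = sigma_ind,
                 sigma_yr = sigma_yr, sigma_resid = sigma_resid,
                 kappa = kappa, eps_ind = eps_ind, eps_yr = eps_yr),
            class = "fidelity_params")
}

## Look up random effects by id; absent ids contribute 0.
.re_lookup <- function(eps, ids) {
  if (length(eps) == 0L) return(numeric(length(ids)))
  out <- unname(eps[as.character(ids)])
  out[is.na(out)] <- 0
  out
}

#' Linear predictor of expected log dispersal distance
#'
#' Computes g = mu + eta_s * s + eta_w * w + eps_yr + beta_f * f +
#' beta_fxw * f * w + eps_ind for each encounter pair, where f is the
#' resolved previous fate (0/1), w the previous-year flood indicator and s
#' the spring index of the later year.
#'
#' @param pairs Data frame of encounter pairs (see [pair_consecutive()]),
#'   with resolved \code{prev_fate} unless \code{fates} is supplied.
#' @param params A [fidelity_params()] object.
#' @param fates Optional integer vector (0/1) overriding
#'   \code{pairs$prev_fate}; required when some fates are missing.
#' @return Numeric vector of expected log dispersal distances (log meters).
#' @export
linear_predictor_g <- function(pairs, params, fates = NULL) {
  f <- if (is.null(fates)) pairs$prev_fate else fates
  if (anyNA(f))
    stop("unresolved missing previous fates; imputation happens in the sampler")
  w <- pairs$flood_prev
  s <- pairs$spring_index
  if (is.null(w)) w <- numeric(nrow(pairs))
  if (is.null(s)) s <- numeric(nrow(pairs))
  if (!all(is.finite(w)) || !all(is.finite(s)))
    stop("non-finite covariates")
  params$mu + params$eta_s * s + params$eta_w * w +
    .re_lookup(params$eps_yr, pairs$year) +
    params$beta_f * f + params$beta_fxw * f * w +
    .re_lookup(params$eps_ind, pairs$individual_id)
}

#' Log density of the location-scale Student t distribution
#'
#' Density of x where (x - loc)/scale follows a Student t with \code{df}
#' degrees of freedom.
#'
#' @param x Numeric vector of evaluation points.
#' @param loc Location parameter (vectorized).
#' @param scale Scale parameter, > 0 (vectorized).
#' @param df Degrees of freedom, > 0 (vectorized).
#' @return Log density, same length as the longest argument.
#' @export
t_log_density <- function(x, loc = 0, scale = 1, df = 1) {
  if (any(scale <= 0) || any(df <= 0))
    stop("scale and df must be positive")
  if (!all(is.finite(x)) || !all(is.finite(loc)))
    stop("non-finite x or loc")
  z <- (x - loc) / scale
  lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi) - log(scale) -
    (df + 1) / 2 * log1p(z^2 / df)
}

#' Fidelity model log likelihood
#'
#' Sum over encounter pairs of the location-scale t log density of log
#' dispersal distance, with fate-specific residual scale and degrees of
#' freedom. Dispersal distances are floored at \code{floor_m} before the log
#' transform so observed 0 m movements stay finite.
#'
#' @inheritParams linear_predictor_g
#' @param floor_m Minimum distance (m) substituted before taking logs
#'   (default 1, below typical handheld GPS accuracy).
#' @return Scalar log likelihood.
#' @export
fidelity_loglik <- function(pairs, params, fates = NULL, floor_m = 1) {
  f <- if (is.null(fates)) pairs$prev_fate else fates
  g <- linear_predictor_g(pairs, params, fates = f)
  logd <- log(pmax(pairs$dispersal_m, floor_m))
  ll <- t_log_density(logd, g, params$sigma_resid[f + 1L], params$kappa[f + 1L])
  if (any(!is.finite(ll)))
    stop("non-finite likelihood term for pair(s) ",
         paste(which(!is.finite(ll)), collapse = ", "))
  sum(ll)
}

#' Probability that a nest of unknown fate failed after its last check
#'
#' For a nest last checked alive at age m, the probability it failed before
#' the end of the 28-day exposure period is 1 minus the product of the daily
#' survival probabilities for ages m..28. This is the Bernoulli success
#' probability of the missing-previous-fate submodel (fate coded 1 = fail).
#'
#' @param last_check_age Nest age in days at the last check (1..28; values
#'   above 28 are clamped with a warning).
#' @param phi Numeric vector of daily survival probabilities for ages 1..28
#'   (in (0, 1]); the product runs over ages \code{last_check_age..28}.
#' @return Failure probability in [0, 1).
#' @export
missing_fate_prob <- function(last_check_age, phi) {
  if (length(phi) != 28L) stop("phi must give daily survival for ages 1..28")
  if (any(phi <= 0) || any(phi > 1)) stop("phi must lie in (0, 1]")
  m <- as.integer(last_check_age)
  if (any(m < 1L)) stop("last_check_age must be >= 1")
  if (any(m > 28L)) {
    warning("last_check_age > 28 clamped to 28")
    m <- pmin(m, 28L)
  }
  # tail products: tp[a] = prod(phi[a:28])
  tp <- rev(cumprod(rev(phi)))
  1 - tp[m]
}

#' Moment-matched beta distribution parameters
#'
#' Converts a (mean, sd) pair into the (alpha, beta) parameters of the beta
#' distribution with those moments, used to build informative priors for
#' daily nest survival probabilities.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy sd^2 < mean (1 - mean).
#' @return Named numeric vector \code{c(alpha, beta)}.
#' @export
beta_prior_from_moments <- function(mean, sd) {
  if (any(mean <= 0) || any(mean >= 1)) stop("mean must be in (0, 1)")
  if (any(sd <= 0)) stop("sd must be positive")
  v <- sd^2
  if (any(v >= mean * (1 - mean)))
    stop("infeasible moments: sd^2 must be < mean * (1 - mean)")
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Age- and year-specific daily survival priors
#'
#' Builds the table of beta prior parameters for the daily nest survival
#' probabilities phi[a, j] that drive the missing-fate submodel: one (alpha,
#' beta) pair per nest age 1..28 and year. The default is a neutral prior
#' with the same mean and sd for every cell; study-specific estimates can be
#' supplied as a CSV of (age, year, mean, sd) via [phi_prior_from_csv()].
#'
#' @param years Integer vector of years to cover.
#' @param mean,sd Prior mean and sd applied to every (age, year) cell.
#' @return Object of class \code{phi_prior}: a list with 28 x n_years
#'   matrices \code{alpha} and \code{beta} (rows = ages, columns = years).
#' @export
default_phi_prior <- function(years, mean = 0.99, sd = 0.005) {
  ab <- beta_prior_from_moments(mean, sd)
  ny <- length(years)
  a <- matrix(ab["alpha"], 28, ny, dimnames = list(1:28, years))
  b <- matrix(ab["beta"], 28, ny, dimnames = list(1:28, years))
  structure(list(alpha = a, beta = b, years = as.integer(years)),
            class = "phi_prior")
}

#' @rdname default_phi_prior
#' @param path CSV file with columns \code{age}, \code{year}, \code{mean},
#'   \code{sd}. Years in \code{years} absent from the file fall back to the
#'   across-year mean of the age-specific means and sds.
#' @export
phi_prior_from_csv <- function(path, years) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("age", "year", "mean", "sd")
  if (!all(req %in% names(x)))
    stop("prior file must have columns: ", paste(req, collapse = ", "))
  prior <- default_phi_prior(years)
  # across-year fallback per age
  mfall <- tapply(x$mean, x$age, mean)
  sfall <- tapply(x$sd, x$age, mean)
  for (jy in seq_along(years)) {
    for (a in 1:28) {
      row <- x[x$age == a & x$year == years[jy], ]
      m <- if (nrow(row)) row$mean[1] else unname(mfall[as.character(a)])
      s <- if (nrow(row)) row$sd[1] else unname(sfall[as.character(a)])
      if (is.na(m) || is.na(s))
        stop("no prior (and no fallback) for age ", a)
      ab <- beta_prior_from_moments(m, s)
      prior$alpha[a, jy] <- ab["alpha"]
      prior$beta[a, jy] <- ab["beta"]
    }
  }
  prior
}

## Draw one phi matrix (28 x n_years) from the beta priors.
.draw_phi <- function(prior) {
  n <- length(prior$alpha)
  matrix(stats::rbeta(n, prior$alpha, prior$beta),
         nrow(prior$alpha), ncol(prior$alpha),
         dimnames = dimnames(prior$alpha))
}

## Column index into the phi prior for a vector of (previous) years; years
## outside the covered range use the nearest covered year.
.phi_year_col <- function(prior, years) {
  idx <- match(years, prior$years)
  if (anyNA(idx)) {
    for (k in which(is.na(idx)))
      idx[k] <- which.min(abs(prior$years - years[k]))
  }
  idx
}

#' Vague prior specification for the fidelity model
#'
#' Default priors: normal(0, sd 10) for mu and all regression coefficients
#' (a "normal(0, 100)" prior read as variance 100), uniform(0, 3) for all
#' standard deviations, and gamma(1, 1) for the t degrees of freedom. The
#' normal variance convention and the uniform upper bound are configurable.
#'
#' @param coef_sd SD of the normal priors on mu and coefficients.
#' @param sd_upper Upper bound of the uniform priors on SDs.
#' @param kappa_shape,kappa_rate Gamma prior parameters for the degrees of
#'   freedom.
#' @param fix_kappa Optional length-2 vector fixing the degrees of freedom
#'   (not sampled); \code{NULL} to estimate them.
#' @return A list of prior settings.
#' @export
fidelity_prior_spec <- function(coef_sd = 10, sd_upper = 3,
                                kappa_shape = 1, kappa_rate = 1,
                                fix_kappa = NULL) {
  list(coef_sd = coef_sd, sd_upper = sd_upper, kappa_shape = kappa_shape,
       kappa_rate = kappa_rate, fix_kappa = fix_kappa)
}

#' Marginalized expected dispersal distance
#'
#' For each posterior draw, computes exp(mu + eta_w w + beta_f f +
#' beta_fxw f w + eps_yr* + eps_ind*) at an average spring (s = 0), where
#' eps* are fresh random-effect draws from their estimated normal
#' distributions (Monte-Carlo marginalization over among-year and
#' among-individual variation). Draws are summarized by the posterior median
#' and a 95% HPDI. The median is used throughout because the mean of the
#' fitted log-t distribution need not exist.
#'
#' @param fit A fitted fidelity model (see [fit_fidelity()]) or any
#'   \code{posterior_chains} object with parameters \code{mu},
#'   \code{beta_f}, \code{beta_fxw}, \code{eta_w}, \code{sigma_ind},
#'   \code{sigma_yr}.
#' @param f Previous fate (0 = success, 1 = fail).
#' @param w Previous-year flood indicator (0/1).
#' @param seed Optional seed for the fresh random-effect draws; fixing it
#'   makes predictions for different (f, w) share the same draws.
#' @param mass HPDI probability mass (default 0.95).
#' @return List with \code{median} (meters), \code{hpdi} (length 2) and the
#'   per-draw predictions \code{draws}.
#' @export
expected_dispersal <- function(fit, f, w = 0, seed = NULL, mass = 0.95) {
  post <- if (inherits(fit, "nestfid_fit")) fit$posterior else fit
  d <- pooled_draws(post, c("mu", "beta_f", "beta_fxw", "eta_w",
                            "sigma_ind", "sigma_yr"))
  if (nrow(d) == 0L) stop("empty posterior")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n <- nrow(d)
  eps_yr <- stats::rnorm(n) * d[, "sigma_yr"]
  eps_ind <- stats::rnorm(n) * d[, "sigma_ind"]
  pred <- exp(d[, "mu"] + d[, "eta_w"] * w + d[, "beta_f"] * f +
                d[, "beta_fxw"] * f * w + eps_yr + eps_ind)
  hp <- if (length(pred) >= ceiling(1 / (1 - mass))) hpdi(pred, mass)
        else range(pred)
  list(median = stats::median(pred), hpdi = hp, draws = pred)
}
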