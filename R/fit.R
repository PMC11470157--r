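## Fitting the two models: block construction for the generic engine,
## latent-fate Gibbs updates, and result containers.

## Interweaving move: with noncentered random effects the likelihood is
## invariant along (coef -> coef + d, z -> z - d x / sc) whenever the
## coefficient multiplies a group-level covariate x, so the full conditional
## of the shift d involves only the priors. With a normal prior on the
## coefficient it is Gaussian and can be Gibbs-sampled exactly, which
## decorrelates intercepts / year-level coefficients from the random
## effects they would otherwise trade off against.
.shift_gibbs <- function(coef, z, sc, x = rep(1, length(z)),
                         prior_prec, prior_mean = 0) {
  if (length(z) == 0L || sc < 1e-8) return(list(coef = coef, z = z))
  a <- sum(x^2) / sc^2 + prior_prec
  b <- sum(x * z) / sc - prior_prec * (coef - prior_mean)
  d <- stats::rnorm(1, b / a, 1 / sqrt(a))
  list(coef = coef + d, z = z - d * x / sc)
}

## Scale interweave: rewrite the random effects in centered form e = sc z,
## Gibbs-sample the scale from its exact conditional given e (the likelihood
## depends on e only, so the conditional involves just the centered normal
## density of e and the uniform(0, upper) prior on sc: an inverse-gamma on
## sc^2 truncated to (0, upper^2), sampled by inverse CDF), then map back to
## z = e / sc. Decorrelates the SDs from the spread of their effects.
.scale_asis <- function(sc, z, upper) {
  n <- length(z)
  if (n < 2L || sc <= 0) return(list(sc = sc, z = z))
  e <- sc * z
  S <- sum(e^2)
  if (S == 0) return(list(sc = sc, z = z))
  shape <- (n - 1) / 2
  rate <- S / 2
  # X = 1/sc^2 ~ gamma(shape, rate) truncated to X > 1/upper^2
  lo <- stats::pgamma(1 / upper^2, shape, rate)
  if (lo >= 1 - 1e-12) return(list(sc = sc, z = z))
  u <- stats::runif(1, lo, 1)
  x <- stats::qgamma(u, shape, rate)
  sc_new <- 1 / sqrt(x)
  list(sc = sc_new, z = e / sc_new)
}

## Same move with a non-Gaussian prior on the coefficient: propose the shift
## from the z-prior part (independence proposal) and Metropolis-correct with
## the coefficient's prior ratio.
.shift_mh <- function(coef, z, sc, x = rep(1, length(z)), prior_ld) {
  if (length(z) == 0L || sc < 1e-8) return(list(coef = coef, z = z))
  a <- sum(x^2) / sc^2
  if (a <= 0) return(list(coef = coef, z = z))
  b <- sum(x * z) / sc
  d <- stats::rnorm(1, b / a, 1 / sqrt(a))
  if (-stats::rexp(1) < prior_ld(coef + d) - prior_ld(coef))
    list(coef = coef + d, z = z - d * x / sc)
  else
    list(coef = coef, z = z)
}

## Shared design preparation for the fidelity model.
.prep_fidelity <- function(pairs, floor_m) {
  n <- nrow(pairs)
  ind <- factor(pairs$individual_id)
  yr <- factor(pairs$year)
  w <- if (!is.null(pairs$flood_prev)) as.numeric(pairs$flood_prev) else numeric(n)
  s <- if (!is.null(pairs$spring_index)) as.numeric(pairs$spring_index) else numeric(n)
  f_obs <- as.integer(pairs$prev_fate)
  mis <- which(is.na(f_obs))
  m <- pairs$prev_last_check_age
  if (is.null(m)) m <- rep(NA_integer_, n)
  m_mis <- as.integer(m[mis])
  if (anyNA(m_mis) && length(mis)) {
    warning("missing last-check age for some unknown-fate pairs; ",
            "assuming age 1 (full exposure window)")
    m_mis[is.na(m_mis)] <- 1L
  }
  m_mis <- pmin(pmax(m_mis, 1L), 28L)
  yr_idx <- as.integer(yr)
  # year-level versions of the year-determined covariates (used by the
  # interweaving moves; NULL when a covariate varies within year)
  w_yr <- w[match(seq_len(nlevels(yr)), yr_idx)]
  s_yr <- s[match(seq_len(nlevels(yr)), yr_idx)]
  if (n && !isTRUE(all(w == w_yr[yr_idx]))) w_yr <- NULL
  if (n && !isTRUE(all(s == s_yr[yr_idx]))) s_yr <- NULL
  list(n = n,
       logd = log(pmax(pairs$dispersal_m, floor_m)),
       ind_idx = as.integer(ind), n_ind = nlevels(ind),
       ind_levels = levels(ind),
       yr_idx = yr_idx, n_yr = nlevels(yr), yr_levels = levels(yr),
       w_yr = w_yr, s_yr = s_yr,
       w = w, s = s, f_obs = f_obs, mis = mis, m_mis = m_mis,
       prev_year = if (!is.null(pairs$prev_year)) pairs$prev_year
                   else pairs$year - 1L)
}

#' Fit the nest-site fidelity model
#'
#' Samples the full posterior of the nest-site fidelity model (location-scale
#' t likelihood for log dispersal distance; previous-fate, flood and
#' spring-timing effects; noncentered individual and year random effects)
#' together with the latent previous fates of unknown-fate pairs, which are
#' Gibbs-sampled each iteration from their Bernoulli full conditionals with
#' failure priors drawn from the age- and year-specific beta priors.
#'
#' @param pairs Data frame of encounter pairs (see [pair_consecutive()] or
#'   [simulate_fidelity_data()]).
#' @param phi_prior Daily-survival prior table ([default_phi_prior()] /
#'   [phi_prior_from_csv()]); defaults to the neutral prior over the years
#'   spanned by the data.
#' @param priors Output of [fidelity_prior_spec()].
#' @param cfg An [mcmc_config()]; defaults to the fast preset.
#' @param floor_m Dispersal floor in meters applied before the log
#'   transform.
#' @return Object of class \code{nestfid_fit} with elements
#'   \code{posterior} (a [posterior_chains()]), \code{summary} (main
#'   parameters), \code{converged} (all main R-hat < 1.1), \code{prep}
#'   (internal design data) and the inputs.
#' @export
fit_fidelity <- function(pairs, phi_prior = NULL,
                         priors = fidelity_prior_spec(),
                         cfg = mcmc_preset("fast"), floor_m = 1) {
  dat <- .prep_fidelity(pairs, floor_m)
  if (is.null(phi_prior)) {
    yrs <- if (dat$n) sort(unique(c(dat$prev_year, pairs$year))) else 2000L
    phi_prior <- default_phi_prior(yrs)
  }
  model <- .fidelity_model(dat, phi_prior, priors)
  post <- run_mcmc(model, cfg)
  main <- c("mu", "beta_f", "beta_fxw", "eta_w", "eta_s",
            "sigma_k0", "sigma_k1", "kappa_k0", "kappa_k1",
            "sigma_ind", "sigma_yr")
  if (!is.null(priors$fix_kappa))
    main <- setdiff(main, c("kappa_k0", "kappa_k1"))
  summ <- summarize_posterior(post, main)
  structure(list(model = "fidelity", posterior = post, summary = summ,
                 converged = all(summ$rhat < 1.1, na.rm = TRUE), pairs = pairs,
                 prep = dat, phi_prior = phi_prior, priors = priors,
                 cfg = cfg, floor_m = floor_m),
            class = "nestfid_fit")
}

## Build the fidelity model block list.
.fidelity_model <- function(dat, phi_prior, priors) {
  n <- dat$n
  coef_sd <- priors$coef_sd
  sd_up <- priors$sd_upper
  fix_kappa <- priors$fix_kappa
  phi_col <- if (length(dat$mis)) .phi_year_col(phi_prior, dat$prev_year[dat$mis]) else integer(0)

  fates <- function(st) {
    f <- dat$f_obs
    if (length(dat$mis)) f[dat$mis] <- st$fmis
    f
  }
  gfun <- function(st, f) {
    st$mu + st$eta_s * dat$s + st$eta_w * dat$w +
      st$sc_yr * st$z_yr[dat$yr_idx] +
      st$beta_f * f + st$beta_fxw * f * dat$w +
      st$sc_ind * st$z_ind[dat$ind_idx]
  }
  pair_ll <- function(st, f) {
    t_log_density(dat$logd, gfun(st, f), st$sig[f + 1L], st$kap[f + 1L])
  }
  full_ll <- function(st) if (n == 0L) 0 else sum(pair_ll(st, fates(st)))

  scalar_rw <- function(name, prior_ld, unit = 1) {
    list(name = name, type = "rw", unit = unit,
         logpost = function(value, st) {
           st[[name]] <- value
           prior_ld(value) + full_ll(st)
         })
  }
  norm_ld <- function(x) stats::dnorm(x, 0, coef_sd, log = TRUE)
  unif_ld <- function(x) ifelse(x > 0 & x < sd_up, 0, -Inf)

  blocks <- list(
    scalar_rw("mu", norm_ld, unit = 0.5),
    scalar_rw("beta_f", norm_ld, unit = 0.5),
    scalar_rw("beta_fxw", norm_ld, unit = 0.5),
    scalar_rw("eta_w", norm_ld, unit = 0.5),
    scalar_rw("eta_s", norm_ld, unit = 0.05),
    scalar_rw("sc_ind", unif_ld, unit = 0.2),
    scalar_rw("sc_yr", unif_ld, unit = 0.2),
    # residual scale by previous fate: components conditionally independent
    # given the fate split
    list(name = "sig", type = "rw", unit = 0.2,
         logpost = function(value, st) {
           lp <- unif_ld(value)
           ok <- is.finite(lp)
           if (any(ok) && n > 0L) {
             st$sig <- ifelse(ok, value, 1)
             f <- fates(st)
             ll <- .group_sum(pair_ll(st, f), f + 1L, 2L)
             lp[ok] <- lp[ok] + ll[ok]
           }
           lp
         })
  )
  if (is.null(fix_kappa)) {
    blocks <- c(blocks, list(
      list(name = "kap", type = "rw", unit = 0.4,
           logpost = function(value, st) {
             lp <- ifelse(value > 0,
                          stats::dgamma(value, priors$kappa_shape,
                                        priors$kappa_rate, log = TRUE), -Inf)
             ok <- is.finite(lp)
             if (any(ok) && n > 0L) {
               st$kap <- ifelse(ok, value, 1)
               f <- fates(st)
               ll <- .group_sum(pair_ll(st, f), f + 1L, 2L)
               lp[ok] <- lp[ok] + ll[ok]
             }
             lp
           })))
  }
  blocks <- c(blocks, list(
    list(name = "z_ind", type = "rw", unit = 1,
         logpost = function(value, st) {
           st$z_ind <- value
           pr <- stats::dnorm(value, log = TRUE)
           if (n == 0L) return(pr)
           pr + .group_sum(pair_ll(st, fates(st)), dat$ind_idx, dat$n_ind)
         }),
    list(name = "z_yr", type = "rw", unit = 1,
         logpost = function(value, st) {
           st$z_yr <- value
           pr <- stats::dnorm(value, log = TRUE)
           if (n == 0L) return(pr)
           pr + .group_sum(pair_ll(st, fates(st)), dat$yr_idx, dat$n_yr)
         }),
    list(name = "interweave", type = "gibbs",
         draw = function(st) {
           pp <- 1 / coef_sd^2
           r <- .shift_gibbs(st$mu, st$z_yr, st$sc_yr, prior_prec = pp)
           st$mu <- r$coef; st$z_yr <- r$z
           r <- .shift_gibbs(st$mu, st$z_ind, st$sc_ind, prior_prec = pp)
           st$mu <- r$coef; st$z_ind <- r$z
           if (!is.null(dat$w_yr)) {
             r <- .shift_gibbs(st$eta_w, st$z_yr, st$sc_yr, x = dat$w_yr,
                               prior_prec = pp)
             st$eta_w <- r$coef; st$z_yr <- r$z
           }
           if (!is.null(dat$s_yr)) {
             r <- .shift_gibbs(st$eta_s, st$z_yr, st$sc_yr, x = dat$s_yr,
                               prior_prec = pp)
             st$eta_s <- r$coef; st$z_yr <- r$z
           }
           r <- .scale_asis(st$sc_yr, st$z_yr, sd_up)
           st$sc_yr <- r$sc; st$z_yr <- r$z
           r <- .scale_asis(st$sc_ind, st$z_ind, sd_up)
           st$sc_ind <- r$sc; st$z_ind <- r$z
           list(mu = st$mu, eta_w = st$eta_w, eta_s = st$eta_s,
                sc_yr = st$sc_yr, sc_ind = st$sc_ind,
                z_yr = st$z_yr, z_ind = st$z_ind)
         })))
  if (length(dat$mis)) {
    mi <- dat$mis
    blocks <- c(blocks, list(
      list(name = "fmis", type = "gibbs",
           draw = function(st) {
             phi <- .draw_phi(phi_prior)
             tp <- apply(phi, 2, function(col) rev(cumprod(rev(col))))
             q <- 1 - tp[cbind(dat$m_mis, phi_col)]  # P(previous nest failed)
             g1 <- st$mu + st$eta_s * dat$s[mi] + st$eta_w * dat$w[mi] +
               st$sc_yr * st$z_yr[dat$yr_idx[mi]] +
               st$sc_ind * st$z_ind[dat$ind_idx[mi]]
             g0 <- g1
             g1 <- g1 + st$beta_f + st$beta_fxw * dat$w[mi]
             ll0 <- t_log_density(dat$logd[mi], g0, st$sig[1], st$kap[1])
             ll1 <- t_log_density(dat$logd[mi], g1, st$sig[2], st$kap[2])
             lp1 <- log(q) + ll1
             lp0 <- log1p(-q) + ll0
             p1 <- 1 / (1 + exp(lp0 - lp1))
             p1[q <= 0] <- 0
             stats::rbinom(length(mi), 1L, p1)
           })))
  }

  init <- function(jitter) {
    st <- list(
      mu = stats::rnorm(1, 0, jitter),
      beta_f = stats::rnorm(1, 0, jitter),
      beta_fxw = stats::rnorm(1, 0, jitter),
      eta_w = stats::rnorm(1, 0, jitter),
      eta_s = stats::rnorm(1, 0, 0.05 * jitter),
      sc_ind = min(max(1.5 + stats::rnorm(1, 0, 0.4 * jitter), 0.05), sd_up - 0.05),
      sc_yr = min(max(1.5 + stats::rnorm(1, 0, 0.4 * jitter), 0.05), sd_up - 0.05),
      sig = pmin(pmax(1.5 + stats::rnorm(2, 0, 0.4 * jitter), 0.05), sd_up - 0.05),
      kap = if (is.null(fix_kappa)) exp(stats::rnorm(2, log(2), 0.3 * jitter))
            else rep_len(fix_kappa, 2L),
      z_ind = stats::rnorm(dat$n_ind),
      z_yr = stats::rnorm(dat$n_yr),
      fmis = stats::rbinom(length(dat$mis), 1L, 0.5)
    )
    st
  }

  monitor <- function(st) {
    out <- c(mu = st$mu, beta_f = st$beta_f, beta_fxw = st$beta_fxw,
             eta_w = st$eta_w, eta_s = st$eta_s,
             sigma_k0 = st$sig[1], sigma_k1 = st$sig[2],
             kappa_k0 = st$kap[1], kappa_k1 = st$kap[2],
             sigma_ind = st$sc_ind, sigma_yr = st$sc_yr)
    if (dat$n_ind) out <- c(out, stats::setNames(st$z_ind, paste0("z_ind[", seq_len(dat$n_ind), "]")))
    if (dat$n_yr) out <- c(out, stats::setNames(st$z_yr, paste0("z_yr[", seq_len(dat$n_yr), "]")))
    if (length(dat$mis)) out <- c(out, stats::setNames(st$fmis, paste0("f_mis[", seq_along(dat$mis), "]")))
    out
  }

  list(init = init, blocks = blocks, monitor = monitor)
}

## Shared design preparation for the survival model: join nest covariates
## from pairs onto intervals by (individual_id, year).
.prep_survival <- function(intervals, pairs) {
  need <- c("nest_id", "individual_id", "year", "length_days", "outcome")
  if (!all(need %in% names(intervals)))
    stop("intervals must have columns: ", paste(need, collapse = ", "))
  key_i <- paste(intervals$individual_id, intervals$year)
  key_p <- paste(pairs$individual_id, pairs$year)
  pm <- match(key_i, key_p)
  if (anyNA(pm))
    stop("no pair covariates for interval(s) of nest(s): ",
         paste(unique(intervals$nest_id[is.na(pm)]), collapse = ", "))
  iv <- intervals
  iv$dispersal_m <- pairs$dispersal_m[pm]
  iv$prev_fate <- pairs$prev_fate[pm]
  iv$prev_last_check_age <- if (!is.null(pairs$prev_last_check_age))
    pairs$prev_last_check_age[pm] else rep(NA_integer_, nrow(iv))
  iv$prev_year <- if (!is.null(pairs$prev_year)) pairs$prev_year[pm]
    else iv$year - 1L
  # the model conditions on dispersal distance: drop nests without it
  keep <- is.finite(iv$dispersal_m)
  iv <- iv[keep, , drop = FALSE]

  nest <- factor(iv$nest_id)
  ind <- factor(iv$individual_id)
  yr <- factor(iv$year)
  nest_idx <- as.integer(nest)
  first <- match(levels(nest), iv$nest_id)  # one row per nest
  f_nest <- as.integer(iv$prev_fate[first])
  mis_nest <- which(is.na(f_nest))
  m_mis <- as.integer(iv$prev_last_check_age[first][mis_nest])
  if (anyNA(m_mis) && length(mis_nest)) m_mis[is.na(m_mis)] <- 1L
  m_mis <- pmin(pmax(m_mis, 1L), 28L)

  list(n = nrow(iv), iv = iv,
       l = as.numeric(iv$length_days), y = as.integer(iv$outcome),
       d = as.numeric(iv$dispersal_m),
       nest_idx = nest_idx, n_nest = nlevels(nest),
       ind_idx = as.integer(ind), n_ind = nlevels(ind),
       yr_idx = as.integer(yr), n_yr = nlevels(yr), yr_levels = levels(yr),
       f_nest = f_nest, mis_nest = mis_nest, m_mis = m_mis,
       prev_year_nest = iv$prev_year[first])
}

#' Fit the nest survival model
#'
#' Samples the posterior of the exposure-interval nest survival model:
#' Bernoulli(phi^l) interval outcomes, logit-linear daily survival with
#' dispersal distance (raw meters), previous fate and their interaction,
#' hierarchical year intercepts pi_j ~ normal(delta, sigma_yr^2)
#' (noncentered) and individual random effects. Missing previous fates are
#' Gibbs-sampled exactly as in the fidelity model.
#'
#' @param intervals Exposure intervals (see [build_exposure_intervals()]).
#' @param pairs Encounter pairs supplying per-nest covariates (dispersal
#'   distance, previous fate, last-check age), matched by
#'   (individual_id, year).
#' @param phi_prior,cfg As in [fit_fidelity()].
#' @param priors Output of [survival_prior_spec()].
#' @return Object of class \code{nestfid_fit}.
#' @export
fit_survival <- function(intervals, pairs, phi_prior = NULL,
                         priors = survival_prior_spec(),
                         cfg = mcmc_preset("fast")) {
  dat <- .prep_survival(intervals, pairs)
  if (is.null(phi_prior)) {
    yrs <- if (dat$n) sort(unique(c(dat$prev_year_nest, dat$iv$year))) else 2000L
    phi_prior <- default_phi_prior(yrs)
  }
  model <- .survival_model(dat, phi_prior, priors)
  post <- run_mcmc(model, cfg)
  main <- c("delta", "gamma_d", "gamma_f", "gamma_dxf",
            "sigma_yr", "sigma_ind")
  summ <- summarize_posterior(post, main)
  structure(list(model = "survival", posterior = post, summary = summ,
                 converged = all(summ$rhat < 1.1, na.rm = TRUE), pairs = pairs,
                 intervals = intervals, prep = dat, phi_prior = phi_prior,
                 priors = priors, cfg = cfg),
            class = "nestfid_fit")
}

## Build the survival model block list.
.survival_model <- function(dat, phi_prior, priors) {
  n <- dat$n
  coef_sd <- priors$coef_sd
  sd_up <- priors$sd_upper
  phi_col <- if (length(dat$mis_nest))
    .phi_year_col(phi_prior, dat$prev_year_nest[dat$mis_nest]) else integer(0)
  mis_iv <- which(dat$nest_idx %in% dat$mis_nest)  # intervals of missing-fate nests
  mis_pos <- match(dat$nest_idx, dat$mis_nest)     # per-interval index into fmis

  fates <- function(st) {
    f <- dat$f_nest[dat$nest_idx]
    if (length(dat$mis_nest)) {
      sub <- !is.na(mis_pos)
      f[sub] <- st$fmis[mis_pos[sub]]
    }
    f
  }
  idx0 <- which(dat$y == 0L)
  iv_ll <- function(st, f) {
    lp <- st$delta + st$sc_yr * st$z_yr[dat$yr_idx] + st$gamma_d * dat$d +
      st$gamma_f * f + st$gamma_dxf * dat$d * f +
      st$sc_ind * st$z_ind[dat$ind_idx]
    ll <- dat$l * stats::plogis(lp, log.p = TRUE)
    ll[idx0] <- .log1mexp(ll[idx0])
    ll
  }
  full_ll <- function(st) if (n == 0L) 0 else sum(iv_ll(st, fates(st)))

  scalar_rw <- function(name, prior_ld, unit = 1) {
    list(name = name, type = "rw", unit = unit,
         logpost = function(value, st) {
           st[[name]] <- value
           prior_ld(value) + full_ll(st)
         })
  }
  norm_ld <- function(x) stats::dnorm(x, 0, coef_sd, log = TRUE)
  unif_ld <- function(x) ifelse(x > 0 & x < sd_up, 0, -Inf)

  blocks <- list(
    scalar_rw("delta", function(x) stats::dlogis(x, log = TRUE), unit = 0.5),
    scalar_rw("gamma_d", norm_ld, unit = 1e-4),
    scalar_rw("gamma_f", norm_ld, unit = 0.5),
    scalar_rw("gamma_dxf", norm_ld, unit = 1e-4),
    scalar_rw("sc_yr", unif_ld, unit = 0.2),
    scalar_rw("sc_ind", unif_ld, unit = 0.2),
    list(name = "z_yr", type = "rw", unit = 1,
         logpost = function(value, st) {
           st$z_yr <- value
           pr <- stats::dnorm(value, log = TRUE)
           if (n == 0L) return(pr)
           pr + .group_sum(iv_ll(st, fates(st)), dat$yr_idx, dat$n_yr)
         }),
    list(name = "z_ind", type = "rw", unit = 1,
         logpost = function(value, st) {
           st$z_ind <- value
           pr <- stats::dnorm(value, log = TRUE)
           if (n == 0L) return(pr)
           pr + .group_sum(iv_ll(st, fates(st)), dat$ind_idx, dat$n_ind)
         }),
    list(name = "interweave", type = "gibbs",
         draw = function(st) {
           ld <- function(x) stats::dlogis(x, log = TRUE)
           r <- .shift_mh(st$delta, st$z_yr, st$sc_yr, prior_ld = ld)
           st$delta <- r$coef; st$z_yr <- r$z
           r <- .shift_mh(st$delta, st$z_ind, st$sc_ind, prior_ld = ld)
           st$delta <- r$coef; st$z_ind <- r$z
           r <- .scale_asis(st$sc_yr, st$z_yr, sd_up)
           st$sc_yr <- r$sc; st$z_yr <- r$z
           r <- .scale_asis(st$sc_ind, st$z_ind, sd_up)
           st$sc_ind <- r$sc; st$z_ind <- r$z
           list(delta = st$delta, sc_yr = st$sc_yr, sc_ind = st$sc_ind,
                z_yr = st$z_yr, z_ind = st$z_ind)
         }))
  if (length(dat$mis_nest)) {
    blocks <- c(blocks, list(
      list(name = "fmis", type = "gibbs",
           draw = function(st) {
             phi <- .draw_phi(phi_prior)
             tp <- apply(phi, 2, function(col) rev(cumprod(rev(col))))
             q <- 1 - tp[cbind(dat$m_mis, phi_col)]
             f1 <- fates(st); f1[mis_iv] <- 1L
             f0 <- fates(st); f0[mis_iv] <- 0L
             ll1 <- .group_sum(iv_ll(st, f1)[mis_iv], mis_pos[mis_iv],
                               length(dat$mis_nest))
             ll0 <- .group_sum(iv_ll(st, f0)[mis_iv], mis_pos[mis_iv],
                               length(dat$mis_nest))
             lp1 <- log(q) + ll1
             lp0 <- log1p(-q) + ll0
             p1 <- 1 / (1 + exp(lp0 - lp1))
             p1[q <= 0] <- 0
             stats::rbinom(length(dat$mis_nest), 1L, p1)
           })))
  }

  init <- function(jitter) {
    list(
      delta = stats::rnorm(1, 0, jitter),
      gamma_d = stats::rnorm(1, 0, 1e-4 * jitter),
      gamma_f = stats::rnorm(1, 0, jitter),
      gamma_dxf = stats::rnorm(1, 0, 1e-4 * jitter),
      sc_yr = min(max(1.5 + stats::rnorm(1, 0, 0.4 * jitter), 0.05), sd_up - 0.05),
      sc_ind = min(max(1.5 + stats::rnorm(1, 0, 0.4 * jitter), 0.05), sd_up - 0.05),
      z_yr = stats::rnorm(dat$n_yr),
      z_ind = stats::rnorm(dat$n_ind),
      fmis = stats::rbinom(length(dat$mis_nest), 1L, 0.5)
    )
  }

  monitor <- function(st) {
    out <- c(delta = st$delta, gamma_d = st$gamma_d, gamma_f = st$gamma_f,
             gamma_dxf = st$gamma_dxf, sigma_yr = st$sc_yr,
             sigma_ind = st$sc_ind)
    if (dat$n_yr) out <- c(out, stats::setNames(st$z_yr, paste0("z_yr[", seq_len(dat$n_yr), "]")))
    if (dat$n_ind) out <- c(out, stats::setNames(st$z_ind, paste0("z_ind[", seq_len(dat$n_ind), "]")))
    if (length(dat$mis_nest)) out <- c(out, stats::setNames(st$fmis, paste0("f_mis[", seq_along(dat$mis_nest), "]")))
    out
  }

  list(init = init, blocks = blocks, monitor = monitor)
}

#' @export
print.nestfid_fit <- function(x, ...) {
  cat("nestfid", x$model, "model fit\n")
  d <- dim(x$posterior$draws)
  cat("  ", d[2], "chains,", d[1], "stored draws each;",
      if (x$converged) "converged (all main R-hat < 1.1)"
      else "NOT converged (some main R-hat >= 1.1)", "\n\n")
  print(x$summary, digits = 4)
  invisible(x)
}
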