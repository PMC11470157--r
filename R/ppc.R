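## Posterior predictive checks: replicate datasets simulated from the
## fitted models (at the drawn random effects and latent fates) and
## Bayesian p-values for the discrepancy statistics.

#' Bayesian p-value
#'
#' Fraction of replicated statistics greater than or equal to the observed
#' statistic. Values outside (0.10, 0.90) are flagged as evidence for lack
#' of fit (attribute \code{"lack_of_fit"}).
#'
#' @param observed Observed value of the statistic.
#' @param replicated Numeric vector of replicated statistic draws (>= 1).
#' @return The p-value in [0, 1], with a logical \code{"lack_of_fit"}
#'   attribute.
#' @export
bayesian_pvalue <- function(observed, replicated) {
  if (length(replicated) < 1L) stop("need at least one replicate")
  p <- mean(replicated >= observed)
  attr(p, "lack_of_fit") <- p <= 0.10 || p >= 0.90
  p
}

#' Posterior predictive replicate statistics
#'
#' For each of \code{n_reps} posterior draws (evenly spaced through the
#' pooled chains), simulates a full replicate dataset from the fitted model
#' --- using the random effects and latent fates exactly as drawn at that
#' iteration --- and computes the discrepancy statistics: the median and
#' standard deviation of log dispersal distance for the fidelity model, and
#' the mean interval outcome for the survival model.
#'
#' @param fit A \code{nestfid_fit}.
#' @param n_reps Number of replicate datasets (must not exceed the number of
#'   stored posterior draws).
#' @return Object of class \code{nestfid_ppc}: a list of one record per
#'   statistic with fields \code{statistic}, \code{observed},
#'   \code{replicated}, \code{bayesian_p} and \code{lack_of_fit}.
#' @export
posterior_predictive_replicates <- function(fit, n_reps = 500) {
  stopifnot(inherits(fit, "nestfid_fit"))
  dr <- pooled_draws(fit$posterior)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (n_reps > nrow(dr))
    stop("n_reps exceeds the ", nrow(dr), " available posterior draws")
  idx <- unique(round(seq(1, nrow(dr), length.out = n_reps)))
  dat <- fit$prep
  getv <- function(row, base, k) {
    if (k == 0L) return(numeric(0))
    unname(row[paste0(base, "[", seq_len(k), "]")])
  }

  if (fit$model == "fidelity") {
    kap_fixed <- fit$priors$fix_kappa
    med <- sd_ <- numeric(length(idx))
    for (r in seq_along(idx)) {
      row <- dr[idx[r], ]
      f <- dat$f_obs
      if (length(dat$mis)) f[dat$mis] <- getv(row, "f_mis", length(dat$mis))
      g <- row["mu"] + row["eta_s"] * dat$s + row["eta_w"] * dat$w +
        row["sigma_yr"] * getv(row, "z_yr", dat$n_yr)[dat$yr_idx] +
        row["beta_f"] * f + row["beta_fxw"] * f * dat$w +
        row["sigma_ind"] * getv(row, "z_ind", dat$n_ind)[dat$ind_idx]
      sig <- c(row["sigma_k0"], row["sigma_k1"])
      kap <- if (is.null(kap_fixed)) c(row["kappa_k0"], row["kappa_k1"])
             else rep_len(kap_fixed, 2L)
      logd_rep <- g + sig[f + 1L] * stats::rt(dat$n, kap[f + 1L])
      med[r] <- stats::median(logd_rep)
      sd_[r] <- stats::sd(logd_rep)
    }
    res <- list(
      .ppc_record("median", stats::median(dat$logd), med),
      .ppc_record("sd", stats::sd(dat$logd), sd_)
    )
  } else {
    mean_rep <- numeric(length(idx))
    for (r in seq_along(idx)) {
      row <- dr[idx[r], ]
      f <- dat$f_nest[dat$nest_idx]
      if (length(dat$mis_nest)) {
        fm <- getv(row, "f_mis", length(dat$mis_nest))
        pos <- match(dat$nest_idx, dat$mis_nest)
        f[!is.na(pos)] <- fm[pos[!is.na(pos)]]
      }
      lp <- row["delta"] + row["sigma_yr"] * getv(row, "z_yr", dat$n_yr)[dat$yr_idx] +
        row["gamma_d"] * dat$d + row["gamma_f"] * f +
        row["gamma_dxf"] * dat$d * f +
        row["sigma_ind"] * getv(row, "z_ind", dat$n_ind)[dat$ind_idx]
      y_rep <- stats::rbinom(dat$n, 1L, stats::plogis(lp)^dat$l)
      mean_rep[r] <- mean(y_rep)
    }
    res <- list(.ppc_record("mean", mean(dat$y), mean_rep))
  }
  structure(res, class = "nestfid_ppc")
}

.ppc_record <- function(statistic, observed, replicated) {
  p <- bayesian_pvalue(observed, replicated)
  list(statistic = statistic, observed = observed, replicated = replicated,
       bayesian_p = as.numeric(p), lack_of_fit = attr(p, "lack_of_fit"))
}

#' @export
print.nestfid_ppc <- function(x, ...) {
  cat("Posterior predictive checks\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.nestfid_ppc <- function(x, ...) {
  do.call(rbind, lapply(x, function(r)
    data.frame(statistic = r$statistic, observed = r$observed,
               bayesian_p = r$bayesian_p, lack_of_fit = r$lack_of_fit,
               n_reps = length(r$replicated), stringsAsFactors = FALSE)))
}
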