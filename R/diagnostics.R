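## Posterior container, convergence diagnostics and posterior summaries:
## split-chain Gelman-Rubin, effective sample size, HPD intervals, sign
## probabilities.

#' Multi-chain posterior draws
#'
#' Constructs a \code{posterior_chains} object from a 3-d array of draws
#' indexed (iteration, chain, parameter). Fitted models return these;
#' the constructor is exported mainly for tests and small utilities.
#'
#' @param draws Numeric array \code{[iteration, chain, parameter]} with
#'   parameter dimnames.
#' @param meta Optional list of run metadata (seed, acceptance rates, ...).
#' @return Object of class \code{posterior_chains}.
#' @export
posterior_chains <- function(draws, meta = list()) {
  stopifnot(length(dim(draws)) == 3L)
  if (is.null(dimnames(draws)[[3]]))
    stop("draws must carry parameter names")
  structure(list(draws = draws, meta = meta), class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  d <- dim(x$draws)
  cat("posterior_chains:", d[2], "chains x", d[1], "stored iterations x",
      d[3], "parameters\n")
  invisible(x)
}

#' Pooled posterior draws for selected parameters
#'
#' Stacks all chains into one matrix (draw x parameter).
#'
#' @param post A \code{posterior_chains} object.
#' @param pars Character vector of parameter names (default: all).
#' @return Numeric matrix with one column per parameter.
#' @export
pooled_draws <- function(post, pars = NULL) {
  pn <- dimnames(post$draws)[[3]]
  if (is.null(pars)) pars <- pn
  miss <- setdiff(pars, pn)
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  d <- dim(post$draws)
  out <- matrix(post$draws[, , pars, drop = FALSE], d[1] * d[2], length(pars))
  colnames(out) <- pars
  out
}

#' Split-chain Gelman-Rubin statistic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (the stricter, now-standard variant): sqrt(var_plus / W) with
#' var_plus = (n-1)/n W + B/n.
#'
#' @param x Numeric matrix of draws, iterations x chains (>= 2 chains,
#'   >= 10 iterations), or a \code{posterior_chains} object together with
#'   \code{par}.
#' @param par Parameter name when \code{x} is a \code{posterior_chains}.
#' @return The R-hat statistic (>= 1 up to floating point error). Chains
#'   with zero variance everywhere return 1 with a warning.
#' @export
gelman_rubin <- function(x, par = NULL) {
  if (inherits(x, "posterior_chains")) x <- x$draws[, , par, drop = TRUE]
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (m < 2L) stop("need at least 2 chains")
  if (n < 10L) stop("need at least 10 draws per chain")
  half <- floor(n / 2)
  s <- cbind(x[seq_len(half), , drop = FALSE],
             x[(n - half + 1):n, , drop = FALSE])
  W <- mean(apply(s, 2, stats::var))
  if (W == 0) {
    warning("zero within-chain variance; R-hat reported as 1 by convention")
    return(1)
  }
  B_over_n <- stats::var(colMeans(s))
  var_plus <- (half - 1) / half * W + B_over_n
  sqrt(var_plus / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence on the
#' chain-averaged autocorrelations, summed across chains.
#'
#' @inheritParams gelman_rubin
#' @return Estimated effective sample size (capped at the total draw count).
#' @export
ess <- function(x, par = NULL) {
  if (inherits(x, "posterior_chains")) x <- x$draws[, , par, drop = TRUE]
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(n * m)
  max_lag <- min(n - 2L, 2000L)
  acfs <- vapply(seq_len(m), function(j) {
    v <- stats::var(x[, j])
    if (v == 0) return(rep(0, max_lag + 1L))
    stats::acf(x[, j], lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1L))
  rho <- rowMeans(acfs)
  # Geyer: sum pairs rho[2t] + rho[2t+1] while positive
  tot <- 0
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair <= 0) break
    tot <- tot + pair
    t <- t + 2L
  }
  min(n * m, n * m / (1 + 2 * tot))
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval of sorted samples spanning a gap of
#' \code{k = ceiling(mass * n)} order statistics, found by exhaustive window
#' search (the usual sample-HPD convention; the interval contains at least
#' \code{mass * n} samples).
#'
#' @param samples Numeric vector of posterior draws.
#' @param mass Probability mass in (0, 1), default 0.95.
#' @return Numeric vector \code{c(lo, hi)}.
#' @export
hpdi <- function(samples, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop("mass must be a single probability in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  if (n < ceiling(1 / (1 - mass)))
    stop("need at least ", ceiling(1 / (1 - mass)), " samples for mass ", mass)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  lo <- x[1:(n - k)]
  hi <- x[(1 + k):n]
  i <- which.min(hi - lo)
  c(lo[i], hi[i])
}

#' Sign probability of a posterior
#'
#' Fraction of draws sharing the sign of the posterior mean, interpreted as
#' the probability the parameter is greater (or less) than zero. Zeros count
#' as matching; a mean of exactly zero is compared against the positive sign
#' with a warning.
#'
#' @param samples Non-empty numeric vector of draws.
#' @return Probability in [0, 1] (about 0.5 for a sign-balanced posterior).
#' @export
sign_probability <- function(samples) {
  if (length(samples) == 0L) stop("empty sample")
  m <- mean(samples)
  if (m == 0) {
    warning("posterior mean is exactly zero; comparing against positive sign")
    return(mean(samples >= 0))
  }
  if (m > 0) mean(samples >= 0) else mean(samples <= 0)
}

#' Posterior summary table
#'
#' Median, 95% HPDI, sign probability, split-chain R-hat and effective
#' sample size for each requested parameter.
#'
#' @param post A \code{posterior_chains} object.
#' @param pars Parameters to summarize (default: all).
#' @param mass HPDI mass.
#' @return Data frame with one row per parameter.
#' @export
summarize_posterior <- function(post, pars = NULL, mass = 0.95) {
  pn <- dimnames(post$draws)[[3]]
  if (is.null(pars)) pars <- pn
  rows <- lapply(pars, function(p) {
    pooled <- as.vector(post$draws[, , p])
    hp <- hpdi(pooled, mass)
    data.frame(parameter = p,
               median = stats::median(pooled),
               hpdi_lo = hp[1], hpdi_hi = hp[2],
               rho = sign_probability(pooled),
               rhat = if (dim(post$draws)[2] >= 2L)
                 suppressWarnings(gelman_rubin(post, p)) else NA_real_,
               ess = ess(post, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.posterior_chains <- function(object, pars = NULL, ...) {
  summarize_posterior(object, pars = pars)
}

#' Write posterior draws as tidy CSV
#'
#' One row per (chain, iteration, parameter) triple.
#'
#' @param post A \code{posterior_chains} object.
#' @param path Output CSV path.
#' @param pars Parameters to write (default: all).
#' @return Invisibly, \code{path}.
#' @export
write_posterior_csv <- function(post, path, pars = NULL) {
  pn <- dimnames(post$draws)[[3]]
  if (is.null(pars)) pars <- pn
  d <- dim(post$draws)
  df <- expand.grid(iteration = seq_len(d[1]), chain = seq_len(d[2]),
                    parameter = pars, stringsAsFactors = FALSE)
  df$value <- as.vector(post$draws[, , pars])
  df <- df[, c("chain", "iteration", "parameter", "value")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
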