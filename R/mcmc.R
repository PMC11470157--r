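## Generic adaptive Metropolis-within-Gibbs engine.
##
## A model is a plain list with:
##   init(jitter)  -> named state list (overdispersed start; must be able to
##                    reach a finite log posterior within a few attempts)
##   blocks        -> list of parameter blocks, visited in order each sweep:
##       rw blocks:    list(name, type = "rw", unit, logpost(value, state))
##                     where logpost returns one conditional log-posterior
##                     value PER COMPONENT of the block; components must be
##                     conditionally independent given the rest of the state
##                     (scalars trivially are). `unit` sets the natural
##                     proposal scale.
##       gibbs blocks: list(name, type = "gibbs", draw(state)) returning a
##                     new value for state[[name]] from its full conditional,
##                     or a named list of state updates (used for joint
##                     interweaving moves along likelihood-invariant
##                     directions).
##   monitor(state) -> named numeric vector of quantities to store.
##
## Proposals are componentwise Gaussian random walks with Robbins-Monro
## scale adaptation toward a target acceptance rate during burn-in only
## (frozen afterwards, so the post-burn-in chain is a fixed Markov kernel).

#' MCMC run configuration
#'
#' @param n_chains Number of chains (default 3).
#' @param n_iterations Iterations per chain including burn-in (default
#'   80000).
#' @param n_burnin Burn-in iterations discarded and used for adaptation
#'   (default 40000; must be < \code{n_iterations}).
#' @param thin Thinning interval for stored draws (default 1).
#' @param seed Integer seed; chain c uses \code{seed + 1000 (c - 1)}.
#' @param adapt_target Target acceptance rate for scale adaptation
#'   (default 0.44, the scalar random-walk optimum).
#' @param init_jitter Multiplier for the overdispersed start jitter (in
#'   units of each block's natural scale).
#' @return A list of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_chains = 3, n_iterations = 80000,
                        n_burnin = 40000, thin = 1, seed = 1,
                        adapt_target = 0.44, init_jitter = 1) {
  if (n_burnin >= n_iterations) stop("n_burnin must be < n_iterations")
  if (n_chains < 1) stop("need at least one chain")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), adapt_target = adapt_target,
                 init_jitter = init_jitter),
            class = "mcmc_config")
}

#' Run-length presets
#'
#' \code{"paper"}: 3 chains of 80000 iterations with 40000 burn-in (the full
#' analysis setting). \code{"fast"}: 3 chains of 10000 iterations with 5000
#' burn-in, used by the recovery suite.
#'
#' @param preset \code{"paper"} or \code{"fast"}.
#' @param seed Seed passed through to [mcmc_config()].
#' @param ... Further overrides for [mcmc_config()].
#' @export
mcmc_preset <- function(preset = c("fast", "paper"), seed = 1, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "paper")
    list(n_chains = 3, n_iterations = 80000, n_burnin = 40000)
  else
    list(n_chains = 3, n_iterations = 10000, n_burnin = 5000)
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(mcmc_config, args)
}

## Elementwise Metropolis acceptance: accept where the log posterior
## difference exceeds log(U). NaN differences (e.g. -Inf minus -Inf) reject.
.mh_accept <- function(lp_diff, log_u) {
  acc <- lp_diff > log_u
  acc[is.na(acc)] <- FALSE
  acc
}

#' Run the adaptive Metropolis-within-Gibbs sampler
#'
#' @param model Model list (see the package source for the block contract);
#'   built internally by [fit_fidelity()] and [fit_survival()].
#' @param cfg An [mcmc_config()].
#' @return A [posterior_chains()] object; \code{meta} holds per-block
#'   post-burn-in acceptance rates and the configuration.
#' @export
run_mcmc <- function(model, cfg = mcmc_config()) {
  blocks <- model$blocks
  nb <- length(blocks)
  is_rw <- vapply(blocks, function(b) b$type == "rw", logical(1))
  n_store <- (cfg$n_iterations - cfg$n_burnin) %/% cfg$thin
  n_post <- cfg$n_iterations - cfg$n_burnin

  chain_list <- vector("list", cfg$n_chains)
  acc_list <- vector("list", cfg$n_chains)
  mon_names <- NULL

  for (ch in seq_len(cfg$n_chains)) {
    set.seed(cfg$seed + 1000L * (ch - 1L))
    state <- NULL
    last_bad <- NULL
    for (attempt in 1:100) {
      st <- model$init(cfg$init_jitter)
      ok <- TRUE
      for (b in blocks[is_rw]) {
        lp <- b$logpost(st[[b$name]], st)
        if (!all(is.finite(lp))) { ok <- FALSE; last_bad <- b$name; break }
      }
      if (ok) { state <- st; break }
    }
    if (is.null(state))
      stop("could not find an initial state with finite log posterior ",
           "(first offending block: ", last_bad, "); state was: ",
           paste(names(st), vapply(st, function(v) paste(signif(utils::head(v, 3), 3), collapse = ","),
                                   character(1)), sep = "=", collapse = "; "))
    scales <- lapply(blocks, function(b)
      if (b$type == "rw") rep_len(b$unit, length(state[[b$name]])) else NULL)
    acc_n <- lapply(blocks, function(b)
      if (b$type == "rw") numeric(length(state[[b$name]])) else NULL)

    if (is.null(mon_names)) mon_names <- names(model$monitor(state))
    store <- matrix(NA_real_, n_store, length(mon_names))
    si <- 0L

    for (it in seq_len(cfg$n_iterations)) {
      adapting <- it <= cfg$n_burnin
      gain <- if (adapting) min(0.25, it^-0.6) else 0
      for (bi in seq_len(nb)) {
        b <- blocks[[bi]]
        if (!is_rw[bi]) {
          res <- b$draw(state)
          # a gibbs block may update several state entries by returning a
          # named list; otherwise it replaces its own entry
          if (is.list(res)) state[names(res)] <- res
          else state[[b$name]] <- res
          next
        }
        cur <- state[[b$name]]
        k <- length(cur)
        if (k == 0L) next
        sc <- scales[[bi]]
        prop <- cur + sc * stats::rnorm(k)
        lp_diff <- b$logpost(prop, state) - b$logpost(cur, state)
        acc <- .mh_accept(lp_diff, -stats::rexp(k))
        if (any(acc)) {
          cur[acc] <- prop[acc]
          state[[b$name]] <- cur
        }
        if (adapting) {
          scales[[bi]] <- sc * exp(gain * ((acc) - cfg$adapt_target))
        } else {
          acc_n[[bi]] <- acc_n[[bi]] + acc
        }
      }
      if (!adapting && (it - cfg$n_burnin) %% cfg$thin == 0L) {
        si <- si + 1L
        store[si, ] <- model$monitor(state)
      }
    }
    chain_list[[ch]] <- store[seq_len(si), , drop = FALSE]
    rates <- lapply(acc_n[is_rw], function(a) a / n_post)
    names(rates) <- vapply(blocks[is_rw], `[[`, character(1), "name")
    acc_list[[ch]] <- rates
  }

  draws <- array(NA_real_, c(n_store, cfg$n_chains, length(mon_names)),
                 dimnames = list(NULL, NULL, mon_names))
  for (ch in seq_len(cfg$n_chains)) draws[, ch, ] <- chain_list[[ch]]
  posterior_chains(draws, meta = list(config = cfg, acceptance = acc_list))
}

## Sum x over groups idx (integers in 1..n); empty groups contribute 0.
.group_sum <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x) == 0L) return(out)
  gs <- rowsum(x, idx)
  out[as.integer(rownames(gs))] <- gs
  out
}
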