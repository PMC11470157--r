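## End-to-end report bundle: parameter summary tables, marginalized
## expected-dispersal table by previous fate x flood, nest-survival-vs-
## dispersal curves by previous fate, and the posterior predictive check
## table.

#' Nest survival curves over a dispersal grid
#'
#' For each posterior draw and previous fate, computes 28-day nest survival
#' at each dispersal distance on a grid, marginalizing over among-year and
#' among-individual variation with fresh random-effect draws per posterior
#' draw (shared across grid points so each draw traces a smooth curve), and
#' summarizes by the posterior median and 95% HPDI.
#'
#' @param fit A fitted survival model.
#' @param d_grid Dispersal distances (m) at which to evaluate.
#' @param seed Optional seed for the fresh random-effect draws.
#' @return Data frame with columns \code{dispersal_m}, \code{prev_fate},
#'   \code{median}, \code{hpdi_lo}, \code{hpdi_hi}.
#' @export
survival_curves <- function(fit, d_grid = seq(0, 1000, by = 50),
                            seed = NULL) {
  stopifnot(inherits(fit, "nestfid_fit"), fit$model == "survival")
  dr <- pooled_draws(fit$posterior,
                     c("delta", "gamma_d", "gamma_f", "gamma_dxf",
                       "sigma_yr", "sigma_ind"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dr)
  e_yr <- stats::rnorm(n) * dr[, "sigma_yr"]
  e_ind <- stats::rnorm(n) * dr[, "sigma_ind"]
  out <- list()
  for (f in 0:1) {
    for (d in d_grid) {
      lp <- dr[, "delta"] + dr[, "gamma_d"] * d + dr[, "gamma_f"] * f +
        dr[, "gamma_dxf"] * d * f + e_yr + e_ind
      s28 <- nest_survival_28(stats::plogis(lp))
      hp <- hpdi(s28, 0.95)
      out[[length(out) + 1L]] <- data.frame(
        dispersal_m = d, prev_fate = f, median = stats::median(s28),
        hpdi_lo = hp[1], hpdi_hi = hp[2])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expected-dispersal table by previous fate and flood
#'
#' Marginalized expected dispersal distance (posterior median and 95% HPDI,
#' meters) for the four previous fate x previous-year flood combinations,
#' with random-effect draws shared across combinations.
#'
#' @param fit A fitted fidelity model.
#' @param seed Seed for the shared fresh random-effect draws (default 1).
#' @return Data frame with one row per (prev_fate, flood_prev) combination.
#' @export
expected_dispersal_table <- function(fit, seed = 1) {
  stopifnot(inherits(fit, "nestfid_fit"), fit$model == "fidelity")
  out <- list()
  for (f in 0:1) {
    for (w in 0:1) {
      ed <- expected_dispersal(fit, f = f, w = w, seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        prev_fate = f, flood_prev = w, median_m = ed$median,
        hpdi_lo = ed$hpdi[1], hpdi_hi = ed$hpdi[2])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the full analysis report
#'
#' Collects parameter summary tables (median, 95% HPDI, sign probability,
#' R-hat, ESS), the expected-dispersal table by previous fate x flood, the
#' 28-day nest survival curves over a dispersal grid by previous fate, and
#' the posterior predictive check table.
#'
#' @param fidelity_fit,survival_fit Fitted models ([fit_fidelity()],
#'   [fit_survival()]); either may be \code{NULL} to omit its tables.
#' @param ppc_fidelity,ppc_survival Optional
#'   [posterior_predictive_replicates()] results.
#' @param d_grid Dispersal grid for the survival curves.
#' @param seed Seed for the marginalization draws (byte-stable output under
#'   a fixed seed).
#' @return Object of class \code{nestfid_report} (a list of data frames).
#' @export
report <- function(fidelity_fit = NULL, survival_fit = NULL,
                   ppc_fidelity = NULL, ppc_survival = NULL,
                   d_grid = seq(0, 1000, by = 50), seed = 1) {
  if (is.null(fidelity_fit) && is.null(survival_fit))
    stop("nothing to report: both fits are missing")
  out <- list()
  if (!is.null(fidelity_fit)) {
    out$fidelity_summary <- fidelity_fit$summary
    out$expected_dispersal <- expected_dispersal_table(fidelity_fit, seed = seed)
  }
  if (!is.null(survival_fit)) {
    out$survival_summary <- survival_fit$summary
    out$survival_curves <- survival_curves(survival_fit, d_grid, seed = seed)
  }
  ppc <- list()
  if (!is.null(ppc_fidelity))
    ppc$fidelity <- cbind(model = "fidelity", as.data.frame(ppc_fidelity))
  if (!is.null(ppc_survival))
    ppc$survival <- cbind(model = "survival", as.data.frame(ppc_survival))
  if (length(ppc)) out$ppc <- do.call(rbind, c(ppc, make.row.names = FALSE))
  structure(out, class = "nestfid_report")
}

#' @export
print.nestfid_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]], digits = 4)
    cat("\n")
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes \code{summary.csv} (both models stacked), \code{ppc.csv},
#' \code{expected_dispersal.csv} and \code{survival_curves.csv}, plus a
#' machine-readable \code{report.json} with everything.
#'
#' @param x A \code{nestfid_report}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "nestfid_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  summ <- list()
  if (!is.null(x$fidelity_summary))
    summ$f <- cbind(model = "fidelity", x$fidelity_summary)
  if (!is.null(x$survival_summary))
    summ$s <- cbind(model = "survival", x$survival_summary)
  if (length(summ)) {
    p <- file.path(dir, "summary.csv")
    utils::write.csv(do.call(rbind, c(summ, make.row.names = FALSE)), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in c("ppc", "expected_dispersal", "survival_curves")) {
    if (!is.null(x[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(x), p, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(c(paths, p))
}
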