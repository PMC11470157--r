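## Single-file model configuration: priors, phi-prior CSV and run settings.

#' Read a model/prior configuration file
#'
#' Loads a YAML file collecting everything a fit needs besides the data:
#' prior settings for both models, an optional daily-survival prior CSV, and
#' an MCMC preset. All keys are optional; omitted ones take the package
#' defaults. Recognized structure:
#'
#' ```yaml
#' fidelity:
#'   coef_sd: 10        # SD of the normal priors on mu and coefficients
#'   sd_upper: 3        # upper bound of the uniform priors on SDs
#'   kappa_shape: 1
#'   kappa_rate: 1
#'   fix_kappa: [10, 10]   # optional: fix the t degrees of freedom
#' survival:
#'   coef_sd: 10
#'   sd_upper: 3
#' phi_prior_csv: priors/phi.csv   # (age, year, mean, sd), relative to the
#'                                 # config file
#' mcmc:
#'   preset: fast       # or "paper"
#'   n_chains: 3        # individual overrides of the preset
#'   seed: 1
#' dispersal_floor_m: 1
#' ```
#'
#' @param path Path to the YAML file.
#' @return List with elements \code{fidelity_priors}, \code{survival_priors},
#'   \code{phi_prior_csv} (absolute path or NULL), \code{cfg} (an
#'   [mcmc_config()]) and \code{floor_m}.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  fid <- do.call(fidelity_prior_spec, utils::modifyList(
    list(), if (is.null(y$fidelity)) list() else y$fidelity))
  sv <- do.call(survival_prior_spec, utils::modifyList(
    list(), if (is.null(y$survival)) list() else y$survival))
  phi_csv <- if (!is.null(y$phi_prior_csv)) {
    p <- y$phi_prior_csv
    if (!file.exists(p)) p <- file.path(dirname(path), y$phi_prior_csv)
    if (!file.exists(p)) stop("phi prior CSV not found: ", y$phi_prior_csv)
    normalizePath(p)
  }
  m <- if (is.null(y$mcmc)) list() else y$mcmc
  preset <- if (is.null(m$preset)) "fast" else m$preset
  m$preset <- NULL
  cfg <- do.call(mcmc_preset, c(list(preset = preset), m))
  list(fidelity_priors = fid, survival_priors = sv, phi_prior_csv = phi_csv,
       cfg = cfg,
       floor_m = if (is.null(y$dispersal_floor_m)) 1 else y$dispersal_floor_m)
}
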