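# Small scenario builders shared across tests.

# A compact scenario: n individuals, each with one run of `len` consecutive
# encounters, over a short study period.
tiny_scenario <- function(n = 40, len = 3, seed = 1, years = 2000:2009,
                          flood_years = c(2004L, 2007L),
                          missing_fate_rate = 0.15, fail_rate = 0.13,
                          fidelity = NULL, survival = NULL,
                          n_censored = 0) {
  scenario_config(
    run_lengths = rep(len, n),
    years = years,
    flood_years = flood_years,
    mean_init_day = stats::setNames(
      150 + seq(-4, 4, length.out = length(years)), years),
    fidelity_params = if (is.null(fidelity)) fidelity_params(
      mu = log(125.5), beta_f = 0.5, beta_fxw = -0.6, eta_s = -0.002,
      eta_w = 0.3, sigma_ind = 0.7, sigma_yr = 0.1,
      sigma_resid = c(0.75, 0.75), kappa = c(10, 10)) else fidelity,
    survival_params = if (is.null(survival)) survival_params(
      delta = stats::qlogis(0.994), gamma_d = -2e-4, gamma_f = -0.115,
      gamma_dxf = 0.004, sigma_yr = 1.177, sigma_ind = 0.176) else survival,
    missing_fate_rate = missing_fate_rate, fail_rate = fail_rate,
    n_censored = n_censored, seed = seed
  )
}

# A noiseless fidelity scenario: no covariate effects, no random effects,
# (near-)zero residual scale, all fates successful.
degenerate_scenario <- function(seed = 1, sigma_resid = 1e-9, mu = log(125.5)) {
  scenario_config(
    run_lengths = rep(2L, 50),
    years = 2000:2005,
    flood_years = integer(0),
    mean_init_day = stats::setNames(rep(150, 6), 2000:2005),
    fidelity_params = fidelity_params(
      mu = mu, beta_f = 0, beta_fxw = 0, eta_s = 0, eta_w = 0,
      sigma_ind = 0, sigma_yr = 0, sigma_resid = rep(sigma_resid, 2),
      kappa = c(10, 10)),
    survival_params = survival_params(delta = stats::qlogis(0.994)),
    missing_fate_rate = 0, fail_rate = 0, seed = seed
  )
}

# Random-walk-free check helper: quantile-based MC tolerance
mc_se <- function(x) stats::sd(x) / sqrt(length(x))
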