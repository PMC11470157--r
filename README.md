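# nestfid

Hierarchical Bayesian models of fine-scale nest-site fidelity and nest
survival for long-term capture-mark-reencounter data on nesting birds —
built around the win-stay lose-switch question: do individuals return to a
nest site after a success and move away after a failure, and does moving
after a failure pay off in higher nest survival?

The package is written for analyses of marked breeding females encountered
on nests in consecutive years (the motivating system is emperor geese on
Alaska's Yukon–Kuskokwim Delta, 2000–2017: 602 consecutive-encounter pairs
of 245 females), but all model machinery is generic.

## The two models

**Nest-site fidelity.** Dispersal distance d between an individual's nests
in consecutive years, on the log scale, with a location-scale Student-t
likelihood whose scale and degrees of freedom depend on the previous nest
fate k (0 = success, 1 = fail):

    log d_ij ~ t(g_ij, sigma_k^2, kappa_k)
    g_ij     = alpha_j + beta_f f_ij-1 + beta_fxw f_ij-1 w_j-1 + eps_ind_i
    alpha_j  = mu + eta_s s_j + eta_w w_j-1 + eps_yr_j

with previous fate f, previous-year major-flood indicator w, early–late
spring index s (days), and normal individual/year random effects. Pairs
with unknown previous fate are not discarded: the fate is a latent
Bernoulli variable whose failure probability is `1 - prod(phi_a,j-1)` over
the nest ages from its last check to day 28, with informative beta priors
on the daily survival probabilities phi. Win-stay lose-switch predicts
beta_f > 0.

**Nest survival.** Visit histories become exposure intervals of length l
with outcome y (1 = survived the interval), and

    y ~ Bernoulli(phi_ij^l)
    logit(phi_ij) = pi_j + gamma_d d_ij + gamma_f f_ij-1
                    + gamma_dxf d_ij f_ij-1 + eps_ind_i,
    pi_j ~ normal(delta, sigma_yr^2)

with dispersal distance in raw meters and the same missing-fate submodel.
Nest survival over the full 28-day exposure period is phi^28. An adaptive
benefit of switching predicts gamma_dxf > 0.

Both models are fit by a native adaptive Metropolis-within-Gibbs sampler
with noncentered random effects, exact-Gibbs interweaving moves for the
intercept/random-effect ridges, and latent-fate Gibbs updates; diagnostics
are split-chain Gelman–Rubin statistics, effective sample sizes, 95% HPD
intervals, sign probabilities, and posterior predictive Bayesian p-values.
See `vignettes/nestfid-methods.Rmd` for the full account.

## Worked example

A calibrated synthetic study (the generator reproduces the motivating
study's structure: 602 pairs, 446/65/91 previous-fate composition, floods
in 2010/2013) and a fidelity fit with short chains:

```r
library(nestfid)

scenario <- default_scenario(seed = 42)
pairs <- simulate_fidelity_data(scenario)
fit <- fit_fidelity(pairs, cfg = mcmc_config(n_chains = 2,
                                             n_iterations = 3000,
                                             n_burnin = 1500, seed = 42))
print(fit)
#> nestfid fidelity model fit
#>    2 chains, 1500 stored draws each; converged (all main R-hat < 1.1)
#>
#>    parameter  median    hpdi_lo  hpdi_hi    rho   rhat   ess
#> 1         mu 4.94089  4.8222801  5.08223 1.0000 1.0027 584.3
#> 2     beta_f 0.30081  0.0142614  0.57372 0.9853 0.9999 254.7
#> 3   beta_fxw 0.33132 -1.1180073  1.67082 0.6963 1.0015 240.1
#> 4      eta_w 0.28153 -0.0083918  0.62464 0.9693 1.0019 263.2
#> ...
```

`mu` is the among-year mean log dispersal (exp(4.94) ≈ 140 m for a
previously successful bird in an average year), `beta_f` the extra log
dispersal after a failed attempt (posterior median 0.30 with sign
probability 0.985: failed birds moved farther — the win-stay lose-switch
signature; this replicate was generated with beta_f = 0.506), and `eta_w`
the flood-year effect. Marginalized expected dispersal distances (medians
over posterior draws with fresh random-effect draws):

```r
expected_dispersal_table(fit, seed = 42)
#>   prev_fate flood_prev median_m hpdi_lo hpdi_hi
#> 1         0          0    141.0   26.32   365.4
#> 2         0          1    187.6   31.39   500.7
#> 3         1          0    191.1   34.12   512.2
#> 4         1          1    344.4   11.90  1563.2
```

Previously failed birds are expected to disperse farther than previously
successful ones (191.1 m vs 141.0 m here). The survival side follows the
same pattern:

```r
visits <- simulate_nest_histories(scenario, pairs)
intervals <- build_exposure_intervals(visits)
sfit <- fit_survival(intervals, pairs, cfg = mcmc_preset("fast", seed = 42))
plogis(sfit$summary$median[sfit$summary$parameter == "delta"])  # daily survival
nest_survival_28(0.994)
#> [1] 0.8449224   # 28-day nest survival at phi = 0.994
posterior_predictive_replicates(sfit, n_reps = 500)
```

A thin command-line wrapper with `simulate` / `fit-fidelity` /
`fit-survival` / `report` subcommands is in `inst/cli/nestfid.R`.

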