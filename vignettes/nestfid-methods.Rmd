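---
title: "Models and methods: nest-site fidelity and nest survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: nest-site fidelity and nest survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nestfid` implements two hierarchical Bayesian models for long-term
capture-mark-reencounter nesting data, motivated by the win-stay lose-switch
hypothesis in subarctic-nesting geese: individuals should return to a nest
site after success and move away after failure, provided habitat quality is
spatially variable but temporally predictable. This vignette documents the
models, their priors and tunable parameters, the sampler, the synthetic-data
generator, and the numerical and design choices a user should know about.

## The nest-site fidelity model

The response is the dispersal distance $d_{i,j}$ (meters) between the nest
of individual $i$ in year $j$ and its nest in year $j-1$, computed as the
Euclidean distance between same-zone UTM coordinates. Distances are modeled
on the log scale with a location-scale Student-$t$ distribution, whose scale
$\sigma_k$ and degrees of freedom $\kappa_k$ depend on the previous nest
fate $k$ (0 = success, 1 = fail), because observed dispersal distances are
highly skewed with occasional multi-kilometer movements:

$$\log d_{i,j} \sim t\!\left(g_{i,j},\, \sigma_k^2,\, \kappa_k\right),$$
$$g_{i,j} = \alpha_j + \beta_f f_{i,j-1} + \beta_{f \times w} f_{i,j-1} w_{j-1}
  + \epsilon_{\mathrm{ind},i},$$
$$\alpha_j = \mu + \eta_s s_j + \eta_w w_{j-1} + \epsilon_{\mathrm{yr},j},$$

with $f_{i,j-1}$ the previous nest fate, $w_{j-1}$ an indicator of a major
flooding event in the previous year, $s_j$ the early-late spring index (a
year's mean nest initiation date minus the long-term mean, in days, so it
sums to zero across years), and zero-centered normal random effects for
individual and year with standard deviations $\varsigma_{\mathrm{ind},d}$
and $\varsigma_{\mathrm{yr},d}$. The win-stay lose-switch prediction is
$\beta_f > 0$.

Priors are vague: normal(0, variance 100) on $\mu$ and all regression
coefficients, uniform(0, 3) on all standard deviations, and gamma(1, 1) on
the degrees of freedom. "normal(0, 100)" is read as variance 100 (SD 10),
the common convention in BUGS-family reports; the prior is vague on the log
scale either way, and `fidelity_prior_spec(coef_sd = )` makes it
configurable. The gamma(1, 1) prior permits $\kappa < 2$, so posterior
moments of the $t$ residual need not exist — all summaries are therefore
posterior medians and HPD intervals, never means.

### Missing previous fates

Some consecutive encounters have unknown previous fates (field crews often
leave before every nest's fate is determined). Rather than discarding those
pairs, the previous fate is a latent Bernoulli variable whose failure
probability is the probability the nest failed *after* it was last checked:

$$f_{i,j-1} \sim \mathrm{Bernoulli}\!\left(1 -
  \prod_{a=m_{i,j-1}}^{28} \phi_{a,j-1}\right),$$

where $m_{i,j-1}$ is the nest's age in days at its last check and
$\phi_{a,j-1}$ are age- and year-specific daily nest survival probabilities
with informative beta priors. The 28-day horizon is the average exposure
period (4 laying days for a 5-egg clutch plus 24 incubation days). The beta
priors are moment-matched from (mean, sd) pairs; study-specific estimates
can be supplied as a CSV of (age, year, mean, sd), with years absent from
the CSV falling back to the across-year mean of the age-specific values. The
shipped default is a neutral mean 0.99, sd 0.005 for every cell — users with
study-area estimates should supply them.

Inside the sampler, each iteration draws $\phi$ from its beta priors and
then Gibbs-samples each latent fate from its exact Bernoulli full
conditional, combining the prior failure probability with the fate-dependent
$t$ likelihood of the observed dispersal distance (full imputation rather
than plug-in means). The $\phi$ draws themselves take no feedback from the
latent fates; their information content for 91 latent Bernoulli trials is
negligible, and this keeps the informative priors authoritative for the
imputation.

## The nest survival model

Nest monitoring histories are converted to exposure intervals: one record
per adjacent pair of visits, of length $l$ days, with outcome 1 if the nest
was alive (or hatched) at the interval's end and 0 if it had failed. A nest
whose fate was never determined is censored; following the source study's
convention the whole nest is dropped (the alternative — keeping its
alive-alive intervals — is available via `keep_censored_intervals`). Failure
is attributed to the whole final interval: the Bernoulli($\phi^l$)
likelihood needs no failure-day imputation.

$$y_{i,j,h} \sim \mathrm{Bernoulli}\!\left(\phi_{i,j}^{\,l_{i,j,h}}\right),$$
$$\mathrm{logit}(\phi_{i,j}) = \pi_j + \gamma_d d_{i,j} + \gamma_f f_{i,j-1}
  + \gamma_{d \times f} d_{i,j} f_{i,j-1} + \varepsilon_{\mathrm{ind},i},
  \qquad \pi_j \sim \mathrm{normal}(\delta, \varsigma^2_{\mathrm{yr},\phi}).$$

Dispersal distance enters in raw meters (no centering or scaling), so
$\gamma_d$ and $\gamma_{d \times f}$ are per-meter coefficients of magnitude
around $10^{-4}$; this matches how such coefficients are reported for this
system. The year intercepts $\pi_j$ are hierarchical (a random intercept
centered on $\delta$), not fixed effects. Priors: logistic(0, 1) on $\delta$
(uniform on the probability scale), normal(0, variance 100) on the
coefficients, uniform(0, 3) on the SDs. Missing previous fates use exactly
the same submodel as the fidelity model (one shared implementation). Records
with missing dispersal distance are excluded — the model conditions on $d$.
Nest survival over a full exposure period is the derived quantity
$\phi^{28}$. The adaptive-significance prediction is
$\gamma_{d \times f} > 0$: dispersing farther after a failure should raise
daily nest survival.

Numerical care: the failure branch $\log(1 - \phi^l)$ is computed as
$\mathrm{log1p}(-\exp(l \log \phi))$ with the usual two-regime `log1mexp`
split, avoiding catastrophic cancellation as $\phi \to 1$; $\log \phi$
itself comes from `plogis(log.p = TRUE)`. A failed interval combined with
$\phi$ numerically equal to 1 yields $-\infty$ (rejected by the sampler; the
standalone likelihood reports it as a data/parameter conflict).

## Sampler

Both models are fit with a native adaptive Metropolis-within-Gibbs engine:

* **Random-walk updates.** Every scalar parameter, and every component of
  the random-effect vectors, gets a Gaussian random-walk proposal whose
  scale adapts by Robbins-Monro toward a 0.44 acceptance rate during
  burn-in and is frozen afterwards, so the retained draws come from a fixed
  Markov kernel. Components of a vector block must be conditionally
  independent given the rest of the state (random effects are, given the
  globals), which allows elementwise accept/reject in one vectorized pass.
* **Noncentered random effects.** All random effects are parameterized as
  $\epsilon = \varsigma z$ with $z \sim \mathrm{normal}(0,1)$ sampled as
  $z$, which removes the funnel between the SDs and their effects.
* **Interweaving moves.** With the noncentered parameterization the
  likelihood is exactly invariant along directions that trade an intercept
  or a year-level coefficient against the year (or individual) effects,
  e.g. $\mu \to \mu + \Delta$, $z_j \to z_j - \Delta/\varsigma$. The full
  conditional of the shift involves only the priors — Gaussian when the
  coefficient's prior is normal (sampled exactly), and handled by a
  partially conjugate independence proposal with a Metropolis correction
  for the logistic prior on $\delta$. A companion move rewrites each
  random-effect block in centered form $e = \varsigma z$ and Gibbs-samples
  the scale from its exact conditional given $e$ (a truncated inverse-gamma
  on $\varsigma^2$, drawn by inverse CDF), then maps back — the standard
  interweaving treatment of the scale/spread trade-off. One such sweep per
  iteration ($\mu$/$\eta_s$/$\eta_w$ against year effects, $\mu$ against
  individual effects, both scales, and analogously $\delta$ in the survival
  model) is what makes the intercepts and SDs mix in thousands rather than
  millions of iterations.
* **Latent fates.** Gibbs-sampled each iteration from their Bernoulli full
  conditionals as described above.
* **Initialization.** Overdispersed starts: prior medians jittered per
  chain (the `init_jitter` multiplier, in units of each block's natural
  scale); initialization retries until the log posterior is finite and
  reports the offending block otherwise.
* **Run lengths.** The `"paper"` preset mirrors the source analysis (3
  chains of 80,000 iterations, 40,000 burn-in). The `"fast"` preset (3 x
  10,000 / 5,000) is what the recovery suite and the acceptance script use;
  with the interweaving moves it yields effective sample sizes in the
  hundreds to thousands for all reported parameters.
* **Determinism.** Chain $c$ seeds R's RNG with `seed + 1000 (c - 1)`;
  identical configuration and data give bit-identical chains.

Convergence is assessed with the split-chain Gelman-Rubin statistic (each
chain halved before computing the potential scale reduction factor — the
stricter, now-standard variant) and an autocorrelation-based effective
sample size using Geyer's initial positive sequence. Posteriors are
summarized by the median, the 95% HPD interval (shortest window over the
sorted draws), and the sign probability $\rho$ — the fraction of draws
sharing the sign of the posterior mean, a directional confidence measure
for regression coefficients. A fit whose main parameters include any
$\hat R \ge 1.1$ is flagged (returned, not discarded).

## Posterior predictive checks

Model fit is checked with Bayesian p-values: for each selected posterior
draw a full replicate dataset is simulated from the model *at the drawn
random effects and latent fates*, a discrepancy statistic is computed, and
the p-value is the fraction of replicates at or above the observed
statistic, flagged outside (0.10, 0.90). The statistics are the median and
SD of log dispersal distance for the fidelity model and the mean interval
outcome for the survival model. Two conventions are fixed here rather than
inherited: the tail direction is $P(\mathrm{rep} \ge \mathrm{obs})$ (the
0.10/0.90 interpretation is direction-symmetric), and the fidelity
statistics are computed on the log scale, where the model is specified.

## The synthetic-data generator

`default_scenario()` encodes the study conditions the package emulates: 245
marked females over 2000-2017, one run of consecutive encounters per
individual with run lengths between 2 and 12 chosen so the roster yields
exactly 602 pairs, major floods in 2010 and 2013, a previous-fate
composition of 446 success / 65 fail / 91 unknown in expectation (known
fates fail at rate 65/511; fates go missing completely at random at rate
91/602), weekly nest visits over a 28-day exposure window, and 92
randomly censored nests leaving 510 known-fate nests. Generating parameter
values are the published posterior medians for this system. Two generating
values are not published and were fixed once as realistic for this system:
the among-year mean log dispersal $\mu = \log 125.5$ (so the marginal
median expected dispersal of previously successful, non-flood birds is
125.5 m), and the residual $t$ parameters $\sigma_k = 0.75$,
$\kappa_k = 10$ for both fates, which reproduce highly skewed distances
with a maximum near 4 km, matching the scale of the observed data.

Missing-fate pairs carry a last-check age drawn uniformly from 14-27 days
(crews leaving in mid-to-late incubation), and their *true* fates are drawn
from the same tail-failure probability the imputation submodel assumes
(using the neutral prior mean), so the generator and the missing-data model
are self-consistent. Nest histories are simulated day by day from the
survival model's own daily probabilities, with visits at ages 0, 7, ...,
28 (optionally jittered by one day).

What the generator does **not** emulate: detection is perfect (every
simulated pair is observed — the source data could not support a detection
or skipped-breeding model either), there is no spatially explicit nest
placement or landscape structure, missingness is MCAR, and each individual
contributes a single unbroken run of years. Passing recovery tests
therefore demonstrate that the estimation machinery recovers the generating
process at the study's sample sizes — not that the models are robust to
detection bias, informative missingness, or spatial confounding in real
data.

## Numerical and design choices

* **Zero distances.** The observed minimum dispersal is 0 m but the model
  is on the log scale; distances are floored at 1 m (below handheld-GPS
  accuracy of about 5 m) before the log transform. The floor is the
  `floor_m` argument.
* **Nest ages** are in days, clamped to 1-28 inside the missing-fate
  submodel; a last-check age above 28 is clamped with a warning. A
  missing-fate pair with no recorded last-check age is treated as last
  checked at age 1 (full exposure window — maximally uncertain), with a
  warning.
* **Pairing** keys on calendar-year arithmetic (years $j$ and $j-1$), not
  encounter order; gaps of two or more years never form a pair.
* **HPD intervals** use the sample convention: the shortest window spanning
  $\lceil 0.95 n \rceil$ order statistics.
* **Sign probability** counts zeros as matching; an exactly-zero posterior
  mean is compared against the positive sign with a warning.
* **Expected dispersal** (the headline quantity) is computed per posterior
  draw as $\exp(\mu + \eta_w w + \beta_f f + \beta_{f \times w} f w +
  \epsilon^*_{\mathrm{yr}} + \epsilon^*_{\mathrm{ind}})$ at an average
  spring ($s = 0$) with *fresh* random-effect draws per posterior draw,
  summarized by the median. This marginalizes predictions over among-year
  and among-individual variation without relying on moments of the log-$t$
  (which may not exist). The exact construction of the corresponding
  published quantity is not fully specified; this Monte-Carlo definition is
  the package's own, and its intervals are accordingly wider than intervals
  on the conditional median would be.
* **Problem sizes in the test suite.** The recovery suite fits one
  study-scale dataset per model with the fast preset; replicated
  calibration checks (daily-survival recovery, PPC calibration) use 10
  replicates at reduced chain lengths, and generator distribution checks
  use up to 50,000 simulated pairs. These sizes were chosen to make the
  suite informative while keeping a full run in the minutes range.

## Known limitations

* The sampler is a random-walk scheme; it is dependency-free and adequate
  at these data sizes, but an HMC backend would scale better to many more
  random effects.
* $\kappa$ under its gamma(1, 1) prior is shrunk toward small values when a
  fate group has few observations; location parameters are insensitive to
  this, but $\sigma_k$ and $\kappa_k$ should be interpreted jointly.
* The interaction coefficient $\gamma_{d \times f}$ is informed by only the
  failed-previous-fate nests (about a fifth of the data), so its posterior
  median varies noticeably between synthetic replicates at the study's
  sample size.
* Patch-scale fidelity, detection probability and skipped breeding are out
  of scope, as in the source analysis.
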