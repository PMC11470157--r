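test_that("the default scenario is calibrated to the study structure", {
  cfg <- default_scenario()
  expect_equal(cfg$flood_years, c(2010L, 2013L))
  expect_equal(cfg$n_individuals, 245L)
  expect_equal(cfg$years, 2000:2017)
  expect_equal(range(cfg$run_lengths), c(2L, 12L))
  # the roster yields exactly 602 pairs by construction
  expect_equal(sum(cfg$run_lengths - 1L), 602L)
  pairs <- simulate_fidelity_data(cfg)
  expect_equal(nrow(pairs), 602L)
})

test_that("scenario invariants are validated", {
  expect_error(scenario_config(run_lengths = integer(0), years = 2000:2005),
               "at least one")
  expect_error(scenario_config(run_lengths = c(2, 1), years = 2000:2005),
               ">= 2 encounters")
  expect_error(scenario_config(run_lengths = 2, years = 2000:2005,
                               missing_fate_rate = 1.2), "missing_fate_rate")
  expect_error(scenario_config(run_lengths = 2, years = 2000:2005,
                               flood_years = 1999), "subset")
  expect_error(scenario_config(run_lengths = 10, years = 2000:2005),
               "longer than the study period")
})

test_that("generated pairs satisfy the encounter-pair invariants", {
  cfg <- default_scenario(seed = 2)
  pairs <- simulate_fidelity_data(cfg)
  expect_true(all(pairs$dispersal_m >= 0))
  expect_true(all(pairs$flood_prev %in% c(0, 1)))
  expect_true(all(pairs$prev_year == pairs$year - 1L))
  expect_true(all(pairs$year %in% cfg$years))
  expect_true(all(na.omit(pairs$prev_fate) %in% 0:1))
  expect_true(all(pairs$prev_last_check_age >= 1 &
                    pairs$prev_last_check_age <= 28))
  # flood indicator agrees with the flood years
  expect_equal(pairs$flood_prev,
               as.numeric(pairs$prev_year %in% cfg$flood_years))
  # spring index is the centered initiation date of the later year
  s <- spring_index(cfg$mean_init_day)
  expect_equal(pairs$spring_index, unname(s[as.character(pairs$year)]))
})

test_that("fate composition matches the study rates in expectation", {
  # pool several seeds to separate rate calibration from binomial noise
  n_mis <- 0; n_fail <- 0; n_known <- 0; n_tot <- 0
  for (seed in 1:5) {
    pairs <- simulate_fidelity_data(default_scenario(seed = seed))
    n_tot <- n_tot + nrow(pairs)
    n_mis <- n_mis + sum(is.na(pairs$prev_fate))
    n_known <- n_known + sum(!is.na(pairs$prev_fate))
    n_fail <- n_fail + sum(pairs$prev_fate == 1, na.rm = TRUE)
  }
  # missing fraction ~ 91/602
  p_mis <- 91 / 602
  expect_lt(abs(n_mis / n_tot - p_mis),
            3 * sqrt(p_mis * (1 - p_mis) / n_tot))
  # failure rate among known fates ~ 65/511
  p_fail <- 65 / 511
  expect_lt(abs(n_fail / n_known - p_fail),
            3 * sqrt(p_fail * (1 - p_fail) / n_known))
})

test_that("simulation is reproducible under the seed and varies across seeds", {
  cfg <- default_scenario(seed = 33)
  p1 <- simulate_fidelity_data(cfg)
  p2 <- simulate_fidelity_data(cfg)
  expect_identical(p1, p2)
  v1 <- simulate_nest_histories(cfg, p1)
  v2 <- simulate_nest_histories(cfg, p1)
  expect_identical(v1, v2)
  p3 <- simulate_fidelity_data(default_scenario(seed = 34))
  expect_false(identical(p1$dispersal_m, p3$dispersal_m))
  # distributional equivalence across seeds (KS on log d)
  big1 <- simulate_fidelity_data(tiny_scenario(n = 5000, len = 3, seed = 1))
  big2 <- simulate_fidelity_data(tiny_scenario(n = 5000, len = 3, seed = 2))
  ks <- suppressWarnings(ks.test(log(big1$dispersal_m), log(big2$dispersal_m)))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate noise collapses dispersal onto exp(mu)", {
  pairs <- simulate_fidelity_data(degenerate_scenario(seed = 6))
  expect_equal(pairs$dispersal_m, rep(125.5, nrow(pairs)), tolerance = 1e-6)
})

test_that("the empirical location of log dispersal matches mu", {
  # large-n median oracle: for f = 0, w = 0, s = 0 the median of log d is mu
  cfg <- tiny_scenario(n = 50000, len = 2, seed = 12, flood_years = integer(0),
                       missing_fate_rate = 0, fail_rate = 0)
  cfg$mean_init_day[] <- 150  # all spring indices zero
  pairs <- simulate_fidelity_data(cfg)
  med <- median(log(pairs$dispersal_m))
  # MC error of a median ~ 1.25 sd/sqrt(n); sd(log d) ~ sqrt(.7^2+.1^2+.79^2)
  expect_equal(med, log(125.5), tolerance = 4 * 1.25 * 1.1 / sqrt(50000))
})

test_that("heavy-tail control: kurtosis approaches normal as kappa grows", {
  fid <- fidelity_params(mu = 5, sigma_ind = 0, sigma_yr = 0,
                         sigma_resid = c(0.8, 0.8), kappa = c(1e7, 1e7))
  cfg <- tiny_scenario(n = 40000, len = 2, seed = 13, fidelity = fid,
                       flood_years = integer(0), missing_fate_rate = 0,
                       fail_rate = 0)
  x <- log(simulate_fidelity_data(cfg)$dispersal_m)
  z <- (x - mean(x)) / sd(x)
  excess <- mean(z^4) - 3
  expect_lt(abs(excess), 6 * sqrt(24 / length(x)))
})

test_that("invalid generator configs error", {
  bad <- degenerate_scenario()
  bad$fidelity_params$sigma_resid <- c(0, 1)
  expect_error(simulate_fidelity_data(bad), "sigma_resid")
  bad2 <- degenerate_scenario()
  bad2$fidelity_params$kappa <- c(-1, 2)
  expect_error(fidelity_params(kappa = c(-1, 2)), "positive")
  bad2$fidelity_params <- unclass(bad2$fidelity_params)
  bad2$fidelity_params$kappa <- c(-1, 2)
  expect_error(simulate_fidelity_data(bad2), "kappa")
})

test_that("nest histories: phi = 1 hatches everything, phi = 0.5 hatches 0.5^28", {
  cfg <- tiny_scenario(n = 300, len = 2, seed = 21, missing_fate_rate = 0)
  pairs <- simulate_fidelity_data(cfg)
  v1 <- simulate_nest_histories(cfg, pairs, phi = 1)
  expect_true(all(tapply(v1$status, v1$nest_id, function(s) s[length(s)]) == "hatched"))
  iv1 <- build_exposure_intervals(v1)
  expect_true(all(iv1$outcome == 1L))

  cfg2 <- tiny_scenario(n = 4000, len = 2, seed = 22, missing_fate_rate = 0)
  pairs2 <- simulate_fidelity_data(cfg2)
  v1 <- simulate_nest_histories(cfg2, pairs2, phi = 0.5)
  hatched <- tapply(v1$status, v1$nest_id, function(s) any(s == "hatched"))
  p <- 0.5^28
  # extremely rare event: expect at most a handful of hatches
  expect_lte(sum(hatched), qbinom(0.9999, length(hatched), p) + 3)

  expect_error(simulate_nest_histories(cfg2, pairs2, phi = 1.01), "invalid config")
  expect_error(simulate_nest_histories(cfg2, pairs2, phi = 0), "invalid config")
})

test_that("empirical daily survival converges to the generating phi", {
  cfg <- tiny_scenario(n = 10000, len = 2, seed = 23, missing_fate_rate = 0)
  pairs <- simulate_fidelity_data(cfg)
  v <- simulate_nest_histories(cfg, pairs, phi = 0.994)
  iv <- build_exposure_intervals(v)
  # binomial daily-survival estimator: survived-days / exposed-days, where a
  # failed interval is approximated by its full length minus one death
  days <- sum(iv$length_days)
  deaths <- sum(iv$outcome == 0)
  phi_hat <- 1 - deaths / days
  # crude exposure attribution biases phi_hat down by < half an interval
  expect_equal(phi_hat, 0.994, tolerance = 0.002)
})

test_that("nest histories respect the visit schedule and censoring count", {
  cfg <- default_scenario(seed = 3)
  pairs <- simulate_fidelity_data(cfg)
  visits <- simulate_nest_histories(cfg, pairs)
  # one nest per pair
  expect_equal(length(unique(visits$nest_id)), nrow(pairs))
  expect_true(all(visits$visit_age %in% seq(0, 28, by = 7)))
  iv <- build_exposure_intervals(visits)
  expect_equal(attr(iv, "summary")$n_censored, 92L)
  expect_equal(attr(iv, "summary")$n_retained, 510L)
  # interval invariant: at most one failed interval per nest, and it is last
  by_nest <- split(iv$outcome, iv$nest_id)
  expect_true(all(vapply(by_nest, function(o)
    sum(o == 0) <= 1 && (!any(o == 0) || o[length(o)] == 0), logical(1))))
})

test_that("write_scenario emits the full CSV bundle with truth", {
  td <- withr::local_tempdir()
  cfg <- tiny_scenario(n = 15, seed = 9)
  paths <- write_scenario(cfg, td)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(file.path(td, "truth.json"))
  expect_equal(truth$fidelity$mu, log(125.5), tolerance = 1e-12)
  expect_equal(truth$survival$gamma_dxf, 0.004)
  enc <- read_encounters(file.path(td, "encounters.csv"))
  expect_true(all(c("easting", "northing", "init_day") %in% names(enc)))
})
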