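make_pairs <- function(n = 20, seed = 1, years = 2000:2004) {
  set.seed(seed)
  data.frame(
    individual_id = sprintf("i%02d", sample(1:8, n, TRUE)),
    year = sample(years, n, TRUE),
    dispersal_m = exp(rnorm(n, 4.8, 1)),
    prev_fate = rbinom(n, 1, 0.3),
    flood_prev = rbinom(n, 1, 0.2),
    spring_index = round(rnorm(n, 0, 3), 1),
    stringsAsFactors = FALSE
  )
}

test_that("linear predictor reduces to its algebraic components", {
  p <- fidelity_params(mu = 4.8, beta_f = 0.506, beta_fxw = -0.647,
                       eta_s = -0.002, eta_w = 0.31)
  base <- data.frame(individual_id = "a", year = 2001, dispersal_m = 100,
                     prev_fate = 0L, flood_prev = 0, spring_index = 0)
  expect_equal(linear_predictor_g(base, p), 4.8)

  fail <- transform(base, prev_fate = 1L)
  expect_equal(linear_predictor_g(fail, p), 4.8 + 0.506)
  # previously failed birds disperse exp(beta_f) times farther
  expect_equal(exp(linear_predictor_g(fail, p) - linear_predictor_g(base, p)),
               exp(0.506), tolerance = 1e-12)
  expect_equal(round(exp(0.506), 3), 1.659)

  both <- transform(base, prev_fate = 1L, flood_prev = 1)
  expect_equal(linear_predictor_g(both, p), 4.8 + 0.31 + 0.506 - 0.647)

  unresolved <- transform(base, prev_fate = NA_integer_)
  expect_error(linear_predictor_g(unresolved, p), "unresolved")
})

test_that("linear predictor picks up named random effects", {
  p <- fidelity_params(mu = 1, eps_ind = c(a = 0.5), eps_yr = c(`2001` = -0.2))
  d <- data.frame(individual_id = c("a", "b"), year = c(2001, 2002),
                  dispersal_m = 1, prev_fate = 0L, flood_prev = 0,
                  spring_index = 0)
  expect_equal(linear_predictor_g(d, p), c(1 + 0.5 - 0.2, 1))
})

test_that("t_log_density matches known values and the normal limit", {
  # Cauchy peak
  expect_equal(t_log_density(0, 0, 1, 1), log(1 / pi), tolerance = 1e-12)
  # normal limit at large df
  for (x in c(-2, 0, 2))
    expect_equal(t_log_density(x, 0.3, 1.2, 1e6),
                 dnorm(x, 0.3, 1.2, log = TRUE), tolerance = 1e-4)
  expect_error(t_log_density(0, 0, -1, 5), "positive")
  expect_error(t_log_density(0, 0, 1, 0), "positive")
  expect_error(t_log_density(NaN, 0, 1, 1), "non-finite")
})

test_that("t_log_density integrates to one", {
  for (par in list(c(0, 1, 1), c(1.5, 0.4, 3), c(-2, 2, 0.7))) {
    int <- integrate(function(x) exp(t_log_density(x, par[1], par[2], par[3])),
                     -Inf, Inf, rel.tol = 1e-10, subdivisions = 2000L)
    expect_equal(int$value, 1, tolerance = 1e-6)
  }
})

test_that("fidelity_loglik equals a term-by-term transcription", {
  pairs <- make_pairs(n = 40, seed = 2)
  params <- fidelity_params(
    mu = 4.7, beta_f = 0.5, beta_fxw = -0.6, eta_s = -0.01, eta_w = 0.3,
    sigma_resid = c(0.8, 1.1), kappa = c(6, 3),
    eps_ind = setNames(rnorm(8, 0, 0.5), sprintf("i%02d", 1:8)),
    eps_yr = setNames(rnorm(5, 0, 0.1), 2000:2004)
  )
  # independent transcription: R's dt() on the standardized residual,
  # looping pair by pair
  oracle <- 0
  for (i in seq_len(nrow(pairs))) {
    r <- pairs[i, ]
    g <- params$mu + params$eta_s * r$spring_index + params$eta_w * r$flood_prev +
      params$eps_yr[[as.character(r$year)]] +
      params$beta_f * r$prev_fate + params$beta_fxw * r$prev_fate * r$flood_prev +
      params$eps_ind[[r$individual_id]]
    s <- params$sigma_resid[r$prev_fate + 1]
    k <- params$kappa[r$prev_fate + 1]
    oracle <- oracle + dt((log(max(r$dispersal_m, 1)) - g) / s, df = k, log = TRUE) - log(s)
  }
  expect_equal(fidelity_loglik(pairs, params), oracle, tolerance = 1e-10)

  # additivity over independent pairs
  expect_equal(fidelity_loglik(pairs[1:2, ], params),
               fidelity_loglik(pairs[1, ], params) +
                 fidelity_loglik(pairs[2, ], params), tolerance = 1e-12)

  # a pair at its own mode contributes the density peak
  one <- pairs[1, ]
  one$prev_fate <- 0L
  g1 <- linear_predictor_g(one, params)
  one$dispersal_m <- exp(g1)
  expect_equal(fidelity_loglik(one, params),
               t_log_density(g1, g1, params$sigma_resid[1], params$kappa[1]))
})

test_that("missing_fate_prob computes tail failure probabilities", {
  expect_equal(missing_fate_prob(10, rep(1, 28)), 0)
  phi <- rep(1, 28); phi[28] <- 0.99
  expect_equal(missing_fate_prob(28, phi), 0.01)
  expect_equal(missing_fate_prob(27, rep(0.99, 28)), 1 - 0.99^2)
  expect_equal(missing_fate_prob(27, rep(0.99, 28)), 0.0199)
  expect_warning(p <- missing_fate_prob(30, rep(0.99, 28)), "clamped")
  expect_equal(p, 1 - 0.99)
  expect_error(missing_fate_prob(10, rep(0.99, 27)), "ages 1..28")
  expect_error(missing_fate_prob(10, rep(0, 28)), "in \\(0, 1\\]")
})

test_that("missing_fate_prob is non-increasing in the last-check age", {
  set.seed(9)
  for (rep in 1:20) {
    phi <- runif(28, 0.9, 0.999)
    q <- vapply(1:28, missing_fate_prob, numeric(1), phi = phi)
    expect_true(all(diff(q) <= 1e-12))
  }
})

test_that("beta_prior_from_moments round-trips and rejects infeasible moments", {
  expect_equal(unname(beta_prior_from_moments(0.5, sqrt(1 / 12))), c(1, 1),
               tolerance = 1e-12)
  ab <- beta_prior_from_moments(0.994, 0.003)
  m <- ab["alpha"] / sum(ab)
  v <- ab["alpha"] * ab["beta"] / (sum(ab)^2 * (sum(ab) + 1))
  expect_equal(unname(m), 0.994, tolerance = 1e-12)
  expect_equal(unname(sqrt(v)), 0.003, tolerance = 1e-12)
  expect_error(beta_prior_from_moments(0.9, 0.3), "infeasible")
  expect_error(beta_prior_from_moments(1.2, 0.1), "in \\(0, 1\\)")
})

test_that("phi prior table honors CSV values with across-year fallback", {
  td <- withr::local_tempdir()
  csv <- file.path(td, "phi.csv")
  grid <- expand.grid(age = 1:28, year = c(2000, 2001))
  grid$mean <- ifelse(grid$year == 2000, 0.99, 0.97)
  grid$sd <- 0.005
  write.csv(grid, csv, row.names = FALSE)
  pr <- phi_prior_from_csv(csv, years = c(2000, 2001, 2002))
  m <- pr$alpha / (pr$alpha + pr$beta)
  expect_equal(unname(m[1, "2000"]), 0.99, tolerance = 1e-10)
  expect_equal(unname(m[5, "2001"]), 0.97, tolerance = 1e-10)
  # 2002 absent from the file: across-year mean of the age-specific means
  expect_equal(unname(m[12, "2002"]), 0.98, tolerance = 1e-10)
})

test_that("expected_dispersal is exact in the degenerate case and under shared draws", {
  # single draw, all SDs zero
  dr <- array(c(4.8, 0.5, -0.6, 0.3, 0, 0), c(1, 1, 6),
              dimnames = list(NULL, NULL,
                              c("mu", "beta_f", "beta_fxw", "eta_w",
                                "sigma_ind", "sigma_yr")))
  post <- posterior_chains(dr)
  expect_equal(expected_dispersal(post, f = 0, w = 0)$median, exp(4.8))
  expect_equal(expected_dispersal(post, f = 1, w = 1)$median,
               exp(4.8 + 0.3 + 0.5 - 0.6))

  # with variability, shared random-effect draws make the f-ratio exact
  set.seed(31)
  n <- 400
  dr2 <- array(c(rnorm(n, 4.8, 0.1), rnorm(n, 0.5, 0.05), rnorm(n, -0.6, 0.1),
                 rnorm(n, 0.3, 0.1), runif(n, 0.5, 0.9), runif(n, 0, 0.2)),
               c(n, 1, 6), dimnames = dimnames(dr))
  post2 <- posterior_chains(dr2)
  e0 <- expected_dispersal(post2, f = 0, w = 0, seed = 99)
  e1 <- expected_dispersal(post2, f = 1, w = 0, seed = 99)
  # per-draw ratio is exp(beta_f); medians need not divide exactly, so check
  # the draw-wise ratio
  expect_equal(e1$draws / e0$draws, exp(dr2[, 1, "beta_f"]), tolerance = 1e-12)
  expect_error(expected_dispersal(posterior_chains(dr2[0, , , drop = FALSE]),
                                  f = 0), "empty posterior|at least")
})
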