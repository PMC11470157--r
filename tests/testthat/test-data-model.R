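test_that("euclidean_distance matches known geometry and rejects bad input", {
  expect_equal(euclidean_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(433000, 6788000), c(433300, 6788400)), 500)
  # symmetry
  expect_equal(euclidean_distance(c(1, 2), c(5, -1)),
               euclidean_distance(c(5, -1), c(1, 2)))
  expect_error(euclidean_distance(c(NA, 0), c(0, 0)), "non-finite")
  expect_error(euclidean_distance(c(Inf, 0), c(0, 0)), "non-finite")
})

test_that("euclidean_distance satisfies the triangle inequality", {
  set.seed(42)
  for (i in 1:200) {
    p <- matrix(runif(6, 0, 1e6), 3, 2)
    d12 <- euclidean_distance(p[1, ], p[2, ])
    d23 <- euclidean_distance(p[2, ], p[3, ])
    d13 <- euclidean_distance(p[1, ], p[3, ])
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("spring_index centers initiation dates on the long-term mean", {
  s <- spring_index(c(`2000` = 150, `2001` = 154, `2002` = 146))
  expect_equal(unname(s), c(0, 4, -4))
  expect_equal(names(s), c("2000", "2001", "2002"))
  expect_equal(unname(spring_index(rep(151, 5), years = 2000:2004)), rep(0, 5))
  expect_equal(unname(spring_index(c(`2000` = 151))), 0)
  expect_error(spring_index(numeric(0)), "at least one year")
})

test_that("spring_index always sums to zero", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:25, 1)
    s <- spring_index(runif(n, 130, 170), years = seq_len(n))
    expect_lt(abs(sum(s)), 1e-9)
  }
})

test_that("pair_consecutive pairs consecutive years only and carries fates", {
  enc <- data.frame(
    individual_id = "a",
    year = c(2003, 2004, 2006),
    easting = c(0, 3, 10), northing = c(0, 4, 10),
    fate = c("success", "fail", "success"),
    stringsAsFactors = FALSE
  )
  p <- pair_consecutive(enc)
  expect_equal(nrow(p), 1L)  # 2005 gap breaks pairing
  expect_equal(p$year, 2004)
  expect_equal(p$dispersal_m, 5)
  expect_equal(p$prev_fate, 0L)

  enc2 <- data.frame(
    individual_id = "b", year = c(2010, 2011),
    easting = c(0, 0), northing = c(0, 30),
    fate = c("unknown", "success"), last_check_age = c(21L, 28L),
    stringsAsFactors = FALSE
  )
  p2 <- pair_consecutive(enc2)
  expect_equal(nrow(p2), 1L)
  expect_true(is.na(p2$prev_fate))      # unknown previous fate kept as missing
  expect_equal(p2$prev_last_check_age, 21L)
})

test_that("pair_consecutive matches a brute-force pair count on a random roster", {
  set.seed(11)
  rows <- list()
  for (i in 1:60) {
    yrs <- sort(sample(2000:2017, sample(2:12, 1)))
    rows[[i]] <- data.frame(
      individual_id = sprintf("i%02d", i), year = yrs,
      easting = runif(length(yrs), 0, 1000),
      northing = runif(length(yrs), 0, 1000),
      fate = sample(c("success", "fail", "unknown"), length(yrs), TRUE),
      stringsAsFactors = FALSE
    )
  }
  enc <- do.call(rbind, rows)
  # independent oracle: count adjacent-year pairs by explicit enumeration
  expected <- 0L
  for (r in rows) {
    for (k in seq_len(nrow(r) - 1L))
      if (r$year[k + 1L] - r$year[k] == 1L) expected <- expected + 1L
  }
  expect_equal(nrow(pair_consecutive(enc)), expected)
})

test_that("gap-free rosters yield encounters minus individuals pairs", {
  set.seed(3)
  rows <- lapply(1:30, function(i) {
    len <- sample(2:8, 1)
    y0 <- sample(2000:2010, 1)
    data.frame(individual_id = sprintf("i%02d", i), year = y0:(y0 + len - 1),
               easting = runif(len), northing = runif(len),
               fate = "success", stringsAsFactors = FALSE)
  })
  enc <- do.call(rbind, rows)
  expect_equal(nrow(pair_consecutive(enc)), nrow(enc) - 30L)
})

test_that("pair_consecutive attaches year covariates when supplied", {
  enc <- data.frame(individual_id = "a", year = 2000:2002,
                    easting = c(0, 3, 3), northing = c(0, 4, 8),
                    fate = "success", stringsAsFactors = FALSE)
  yrs <- data.frame(year = 2000:2002, flood = c(1L, 0L, 0L),
                    mean_init_day = c(150, 154, 146))
  p <- pair_consecutive(enc, years = yrs)
  expect_equal(p$flood_prev, c(1L, 0L))       # w_{j-1}
  expect_equal(p$spring_index, c(4, -4))      # s_j
})

test_that("build_exposure_intervals handles hatch, failure and censoring", {
  v <- data.frame(nest_id = "n1", visit_age = c(5, 12, 19, 26),
                  status = c("alive", "alive", "alive", "hatched"),
                  stringsAsFactors = FALSE)
  iv <- build_exposure_intervals(v)
  expect_equal(iv$length_days, c(7, 7, 7))
  expect_equal(iv$outcome, c(1L, 1L, 1L))

  v2 <- data.frame(nest_id = "n2", visit_age = c(5, 12, 19),
                   status = c("alive", "alive", "failed"),
                   stringsAsFactors = FALSE)
  iv2 <- build_exposure_intervals(v2)
  expect_equal(iv2$length_days, c(7, 7))
  expect_equal(iv2$outcome, c(1L, 0L))

  # fate never determined: censored nest dropped by default ...
  v3 <- data.frame(nest_id = "n3", visit_age = c(5, 12),
                   status = c("alive", "alive"), stringsAsFactors = FALSE)
  iv3 <- build_exposure_intervals(v3)
  expect_equal(nrow(iv3), 0L)
  expect_equal(attr(iv3, "censored"), "n3")
  # ... but its alive-alive intervals can be retained on request
  iv3b <- build_exposure_intervals(v3, keep_censored_intervals = TRUE)
  expect_equal(iv3b$length_days, 7)
  expect_equal(iv3b$outcome, 1L)

  expect_error(build_exposure_intervals(
    data.frame(nest_id = "n4", visit_age = c(5, 5),
               status = c("alive", "alive"))), "non-monotone")
})

test_that("exposure is conserved: interval lengths sum to monitored span", {
  set.seed(5)
  for (i in 1:30) {
    ages <- sort(sample(0:28, sample(3:6, 1)))
    k <- length(ages)
    status <- c("alive", sample(c("alive", "failed", "hatched", "unknown"),
                                k - 1, TRUE, prob = c(.6, .2, .15, .05)))
    v <- data.frame(nest_id = "x", visit_age = ages, status = status,
                    stringsAsFactors = FALSE)
    iv <- build_exposure_intervals(v, keep_censored_intervals = TRUE)
    term <- match(TRUE, status %in% c("failed", "hatched"))
    last <- if (is.na(term)) max(which(status == "alive")) else term
    expect_equal(sum(iv$length_days), ages[last] - ages[1])
  }
})

test_that("input readers and preprocessing writer round-trip through CSV", {
  cfg <- tiny_scenario(n = 12, seed = 4)
  pairs <- simulate_fidelity_data(cfg)
  enc <- as_encounters(pairs, cfg)
  visits <- simulate_nest_histories(cfg, pairs)

  td <- withr::local_tempdir()
  write.csv(enc, file.path(td, "encounters.csv"), row.names = FALSE)
  write.csv(visits, file.path(td, "visits.csv"), row.names = FALSE)
  write.csv(scenario_years(cfg)[, c("year", "flood", "mean_init_day")],
            file.path(td, "years.csv"), row.names = FALSE)

  enc2 <- read_encounters(file.path(td, "encounters.csv"))
  yrs <- read_years(file.path(td, "years.csv"))
  p2 <- pair_consecutive(enc2, years = yrs)
  # pairing the synthesized coordinates reproduces the generated distances
  key1 <- paste(pairs$individual_id, pairs$year)
  key2 <- paste(p2$individual_id, p2$year)
  expect_setequal(key1, key2)
  expect_equal(p2$dispersal_m[match(key1, key2)], pairs$dispersal_m,
               tolerance = 1e-8)
  expect_equal(p2$flood_prev[match(key1, key2)], pairs$flood_prev)

  iv <- build_exposure_intervals(read_visits(file.path(td, "visits.csv")))
  paths <- write_preprocessed(p2, iv, file.path(td, "out"))
  expect_true(all(file.exists(paths)))
  summ <- jsonlite::read_json(paths["summary"])
  expect_equal(summ$pairs$n_pairs, nrow(pairs))
})
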