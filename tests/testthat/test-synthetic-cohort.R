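test_that("exposure config rejects invalid correlation and scale inputs", {
  bad <- diag(6); bad[1, 2] <- bad[2, 1] <- 2  # eigenvalue < 0
  expect_error(exposure_config(corr = bad), "smallest eigenvalue")
  expect_error(exposure_config(sigma = c(-1, 1, 1, 1, 1, 1)), "sigma")
  asym <- default_constituent_corr(); asym[1, 2] <- asym[1, 2] + 0.01
  expect_error(exposure_config(corr = asym), "symmetric")
})

test_that("independent constituents stay empirically uncorrelated", {
  cfg <- exposure_config(corr = diag(6), closure_mode = "exact_sum")
  e <- sample_exposures(cfg, n = 10000, seed = 5)
  r <- cor(e[, CONSTITUENTS])
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("default correlation structure induces strong positive correlations", {
  corr <- default_constituent_corr()
  off <- corr[upper.tri(corr)]
  expect_true(all(off >= 0.51 & off <= 0.99))
  e <- sample_exposures(exposure_config(), n = 8000, seed = 6)
  r <- cor(e[, CONSTITUENTS])
  expect_true(all(r[upper.tri(r)] > 0.4))
})

test_that("exact_sum closure holds to machine precision and all values are non-negative", {
  cfg <- exposure_config(closure_mode = "exact_sum")
  e <- sample_exposures(cfg, n = 500, seed = 7)
  expect_equal(max(abs(e$pm25 - rowSums(e[, CONSTITUENTS]))), 0,
               tolerance = 1e-12)
  expect_true(all(as.matrix(e) >= 0))
})

test_that("generation is bit-identical under a repeated seed", {
  a <- simulate_cohort(n = 300, seed = 17)
  b <- simulate_cohort(n = 300, seed = 17)
  expect_identical(a, b)
  c <- simulate_cohort(n = 300, seed = 18)
  expect_false(identical(a$BC, c$BC))
})

test_that("covariate sampling matches configured frequencies and handles degenerate configs", {
  cfg <- covariate_config()
  n <- 20000
  cv <- sample_covariates(cfg, n, seed = 8)
  for (nm in names(cfg$categorical)) {
    p <- cfg$categorical[[nm]]
    emp <- table(cv[[nm]]) / n
    band <- 3 * sqrt(p * (1 - p) / n)
    expect_true(all(abs(emp - p) <= band),
                label = paste("frequencies of", nm, "within 3-SE band"))
  }
  # degenerate probability vector gives a constant column
  cfg2 <- covariate_config()
  cfg2$categorical$gender <- c(female = 1, male = 0)
  cv2 <- sample_covariates(cfg2, 200, seed = 9)
  expect_true(all(cv2$gender == "female"))
  # malformed probabilities are rejected
  expect_error(covariate_config(categorical = list(gender = c(f = 0.6, m = 0.5))),
               "sum to")
})

test_that("age is truncated to the eligibility window", {
  cv <- sample_covariates(covariate_config(), 5000, seed = 10)
  expect_true(all(cv$age >= 35 & cv$age <= 75))
})

test_that("logistic outcome calibration hits the target prevalence", {
  cfg <- covariate_config()
  co <- cbind(sample_covariates(cfg, 50000, seed = 11),
              sample_exposures(exposure_config(), 50000, seed = 12))
  oc <- outcome_config(true_beta = c(BC = 0), target_prevalence = 0.28143,
                       seed = 13)
  co <- assign_outcome(co, oc)
  expect_gte(mean(co$high_risk), 0.276)
  expect_lte(mean(co$high_risk), 0.286)
  # with nonzero effects the calibration still holds in expectation
  oc2 <- outcome_config(true_beta = c(BC = log(1.493)),
                        target_prevalence = 0.28143, seed = 14)
  co2 <- assign_outcome(co[setdiff(names(co), c("risk", "high_risk"))], oc2)
  expect_lt(abs(mean(co2$risk) - 0.28143), 0.005)
})

test_that("calibrated intercept is minus beta-x-bar in the symmetric case", {
  co <- data.frame(x = c(-2, -1, 0, 1, 2))
  oc <- outcome_config(true_beta = c(x = 0.7), target_prevalence = 0.5,
                       seed = 15)
  co <- assign_outcome(co, oc)
  # symmetric covariate, target 0.5 -> alpha ~ -beta * mean(x) = 0
  expect_lt(abs(attr(co, "intercept")), 0.01)
})

test_that("unreachable prevalence targets are reported, not clipped", {
  co <- data.frame(x = rep(0, 100))
  oc <- outcome_config(true_beta = c(x = 1), target_prevalence = 1 - 1e-10,
                       seed = 16)
  expect_error(assign_outcome(co, oc), "unreachable")
})

test_that("window averaging uses exactly the window's months before baseline", {
  bd <- as.Date("2016-07-01")
  b <- 2016 * 12 + 6  # absolute index of the baseline month
  idx <- (b - 36):(b - 1)
  s <- data.frame(id = 1L, pollutant = "pm25",
                  year = idx %/% 12, month = idx %% 12 + 1,
                  value = 80.16)
  attr(s, "baseline_date") <- bd
  expect_equal(window_average(s, 3)$pm25, 80.16)
  s$value <- 1:36
  expect_equal(window_average(s, 3)$pm25, 18.5)
  # 35 of 36 months present: name the first missing month
  expect_error(window_average(s[-1, ], 3), "2013-07")
  # drop mode excludes the participant and audits it
  wa <- window_average(s[-1, ], 3, on_missing = "drop")
  expect_equal(nrow(wa), 0)
  expect_equal(attr(wa, "n_dropped"), 1)
  expect_error(window_average(s, 4), "3, 5, 8, 10")
})

test_that("generated monthly series reproduce cross-sectional exposures when constant", {
  co <- default_cohort()[1:50, ]
  s <- generate_monthly_series(co, pollutants = c("pm25", "BC"),
                               n_months = 120, trend = 0, season_amp = 0,
                               noise_sd = 0, seed = 20)
  wa <- window_average(s, 3)
  m <- merge(co, wa, by = "id", suffixes = c("", ".w"))
  expect_equal(m$pm25.w, m$pm25, tolerance = 1e-12)
  expect_equal(m$BC.w, m$BC, tolerance = 1e-12)
  wa10 <- window_average(s, 10)
  expect_equal(merge(co, wa10, by = "id", suffixes = c("", ".w"))$BC.w,
               m$BC, tolerance = 1e-12)
})

test_that("exclusion cascade audits each step and rejects infeasible counts", {
  res <- apply_exclusions(100, 0, 0, 0)
  expect_equal(res$remaining, 100)
  expect_equal(nrow(res$audit), 4)
  expect_error(apply_exclusions(10, 5, 6, 0), "negative")
  expect_error(apply_exclusions(10, -1, 0, 0), ">= 0")
})
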