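test_that("proportion of total mass is in percent with guarded inputs", {
  expect_equal(round_half_up(compute_proportion(5.190, 75.238), 3), 6.898)
  expect_equal(compute_proportion(3, 3), 100)
  expect_error(compute_proportion(1, 0), "> 0")
  expect_warning(p <- compute_proportion(5, 4), "exceeds")
  expect_equal(p, 125)
})

test_that("total-mass residuals match hand OLS and are orthogonal to mass", {
  r <- compute_residual(c(1, 2, 4), c(1, 2, 3))
  expect_equal(r, c(1 / 6, -1 / 3, 1 / 6), tolerance = 1e-12)
  # perfectly linear constituent leaves no residual
  m <- 1:20
  expect_equal(compute_residual(2 + 0.5 * m, m), rep(0, 20),
               tolerance = 1e-12)
  # orthogonality and zero mean on arbitrary data
  set.seed(31)
  m2 <- rnorm(500, 75, 10)
  c2 <- 0.07 * m2 + rnorm(500)
  r2 <- compute_residual(c2, m2)
  expect_lt(abs(mean(r2)), 1e-10)
  expect_lt(abs(cor(r2, m2)), 1e-10)
  expect_lt(abs(sum(r2 * m2)), 1e-7)
  expect_error(compute_residual(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_error(compute_residual(c(1, 2), c(1, 2)), "3 observations")
})

test_that("the three methods produce the full result-table shape", {
  co <- default_cohort()[1:2000, ]
  tab <- run_constituent_models(co, models = c(1, 2))
  expect_equal(nrow(tab), 38)  # 2 models x (7 + 6 + 6)
  expect_equal(sum(tab$method == "concentration"), 14)
  expect_equal(sum(tab$method == "proportion"), 12)
  expect_equal(sum(tab$method == "residual"), 12)
  expect_true(all(tab$converged))
  expect_true(all(tab$ci_low <= tab$or & tab$or <= tab$ci_high))
})

test_that("proportions close to 100% under exact mass closure and fits stay full rank", {
  co <- closure_cohort()
  props <- sapply(CONSTITUENTS, function(p)
    compute_proportion(co[[p]], co$pm25))
  expect_equal(max(abs(rowSums(props) - 100)), 0, tolerance = 1e-9)
  tab <- run_proportion_analysis(co, model = 1)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$converged))
})

test_that("mass-orthogonality makes the residual slope insensitive to total mass", {
  co <- closure_cohort()
  r <- compute_residual(co$BC, co$pm25)
  # in the linear model orthogonal regressors decouple exactly
  lm0 <- coef(lm(co$high_risk ~ r))[["r"]]
  lm1 <- coef(lm(co$high_risk ~ r + co$pm25))[["r"]]
  expect_lt(abs(lm1 - lm0), 1e-10)
  # in the logistic model the decoupling is asymptotic: when total mass has
  # no residual effect the slope moves by far less than its standard error
  set.seed(88)
  co$high_risk <- rbinom(nrow(co), 1, plogis(-1 + 0.3 * r))
  co$.resid <- r
  f0 <- fit_logistic(build_design(co, model_spec(".resid", model = 1)))
  f1 <- fit_logistic(build_design(co, model_spec(".resid", model = 1,
                                                 extra = "pm25")))
  expect_lt(abs(f1$beta - f0$beta), 0.2 * f0$se)
})

test_that("residual method carries no signal when only total mass matters", {
  # outcome depends on m alone; residuals are orthogonal to m, so residual
  # odds ratios should sit near 1
  co <- simulate_cohort(
    n = 12000, seed = 404,
    outcome_cfg = outcome_config(true_beta = c(pm25 = 0.03), seed = 405))
  tab <- run_residual_analysis(co, model = 1)
  expect_true(all(tab$ci_low < 1 & 1 < tab$ci_high |
                    abs(log(tab$or)) < 0.1))
})

test_that("concentration analysis recovers a known black-carbon effect", {
  reps <- 60L
  covered <- 0L
  for (r in seq_len(reps)) {
    co <- simulate_cohort(
      n = 2000, seed = 7000 + r,
      outcome_cfg = outcome_config(true_beta = c(BC = log(1.493)),
                                   seed = 8000 + r))
    fr <- fit_logistic(build_design(co, model_spec("BC", model = 1)))
    covered <- covered + (fr$ci_low <= 1.493 && 1.493 <= fr$ci_high)
  }
  # nominal 95% coverage; allow the usual binomial slack
  expect_gte(covered / reps, 0.85)
})

test_that("permuting the exposure against the outcome nulls the association", {
  co <- default_cohort()
  set.seed(55)
  co$BC <- sample(co$BC)
  fr <- fit_logistic(build_design(co, model_spec("BC", model = 1)))
  expect_true(fr$ci_low < 1 && 1 < fr$ci_high)
})
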