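test_that("design builder produces the documented column layouts", {
  co <- default_cohort()
  d1 <- build_design(co, model_spec("BC", model = 1))
  expect_equal(ncol(d1$X), 2)
  expect_equal(colnames(d1$X), c("(Intercept)", "BC"))
  d2 <- build_design(co, model_spec("BC", model = 2))
  # intercept + exposure + sum(levels - 1) over the 8 Model-2 covariates:
  # gender 1, marital 1, education 2, income 2, PA 2, high-fat 1,
  # drinking 2, fruit/veg 1 = 12
  expect_equal(ncol(d2$X), 2 + 12)
  # a missing covariate value drops exactly that row (complete-case)
  co2 <- co
  co2$income[5] <- NA
  d3 <- build_design(co2, model_spec("BC", model = 2))
  expect_equal(d3$n, d2$n - 1)
  # constant non-intercept columns are warned about by name
  co3 <- co
  co3$gender <- factor("female", levels = c("female", "male"))
  expect_warning(build_design(co3, model_spec("BC", model = 2)), "gender")
})

test_that("single-binary-predictor fit equals the 2x2 cross-product ratio", {
  d <- design_2x2(30, 70, 10, 90)
  fr <- fit_logistic(d$X, d$y, term = "exposure")
  expect_equal(fr$beta, log(27 / 7), tolerance = 1e-8)
  expect_equal(fr$or, 27 / 7, tolerance = 1e-7)
  expect_true(fr$converged)
  expect_lt(fr$grad_norm, 1e-8)
  # exactly balanced table: no association, beta = 0
  d0 <- design_2x2(25, 25, 25, 25)
  fr0 <- fit_logistic(d0$X, d0$y, term = "exposure")
  expect_equal(fr0$beta, 0, tolerance = 1e-10)
  expect_equal(fr0$or, 1, tolerance = 1e-10)
})

test_that("Wald interval and result invariants hold", {
  d <- design_2x2(30, 70, 10, 90)
  fr <- fit_logistic(d$X, d$y, term = "exposure")
  expect_equal(fr$ci_low, exp(fr$beta - 1.96 * fr$se))
  expect_equal(fr$ci_high, exp(fr$beta + 1.96 * fr$se))
  expect_true(fr$ci_low <= fr$or && fr$or <= fr$ci_high)
  expect_gt(fr$or, 0)
  expect_gt(fr$n, length(fr$coefficients))
})

test_that("rescaling the exposure rescales the slope exactly", {
  co <- default_cohort()[1:1500, ]
  f1 <- fit_logistic(build_design(co, model_spec("BC", model = 1)))
  f2 <- fit_logistic(build_design(co, model_spec("BC", model = 1,
                                                 scale = 10)))
  expect_equal(f2$beta, f1$beta / 10, tolerance = 1e-8)
})

test_that("rank-deficient designs error; separation is flagged loudly", {
  co <- default_cohort()[1:200, ]
  X <- cbind(1, co$BC, co$BC * 2)
  expect_error(fit_logistic(X, co$high_risk), "rank deficient")
  # perfectly separated toy data
  xs <- c(-(5:1), 1:5)
  ys <- c(rep(0, 5), rep(1, 5))
  expect_warning(fr <- fit_logistic(cbind(1, x = xs), ys, term = "x"),
                 "separation|converge")
  expect_true(fr$separation)
  expect_false(fr$converged)
})

test_that("production fitter agrees with the derivative-free oracle on small instances", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(15:30, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    eta <- 0.3 + 0.8 * X[, 2] - 0.5 * X[, 3]
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) next
    fr <- tryCatch(suppressWarnings(fit_logistic(X, y, term = "x1")),
                   error = function(e) NULL)
    if (is.null(fr) || fr$separation) next
    orc <- suppressWarnings(oracle_fit(X, y))
    expect_lt(max(abs(fr$coefficients - orc$coefficients)), 1e-6)
  }
})

test_that("intercept-only oracle returns the empirical logit", {
  y <- c(rep(1, 7), rep(0, 13))
  orc <- oracle_fit(matrix(1, 20, 1), y)
  expect_equal(unname(orc$coefficients), qlogis(7 / 20), tolerance = 1e-6)
  # all-zero response: separation diagnostic
  expect_warning(oracle_fit(matrix(1, 10, 1), rep(0, 10)), "separation")
  expect_error(oracle_fit(matrix(1, 50, 1), rep(1, 50)), "30 rows")
})

test_that("percent excess risk converts odds ratios to the printed scale", {
  expect_equal(percent_excess(1.493), 49.3)
  expect_equal(percent_excess(1.285), 28.5)
  expect_equal(percent_excess(1.0), 0.0)
  expect_error(percent_excess(0), "> 0")
})

test_that("95% Wald intervals cover the truth at the nominal rate", {
  beta_true <- 0.5
  covered <- 0L
  reps <- 300L
  n <- 1500L
  for (r in seq_len(reps)) {
    set.seed(5000 + r)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + beta_true * x))
    fr <- fit_logistic(cbind(1, x = x), y, term = "x")
    lo <- fr$beta - 1.96 * fr$se
    hi <- fr$beta + 1.96 * fr$se
    covered <- covered + (lo <= beta_true && beta_true <= hi)
  }
  expect_gte(covered / reps, 0.92)
  expect_lte(covered / reps, 0.975)
})
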