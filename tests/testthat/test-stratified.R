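test_that("subgroup fits partition the cohort and drop the stratifier from covariates", {
  co <- default_cohort()
  sub <- fit_subgroups(co, "BC", "income", model = 2)
  expect_equal(nrow(sub), 3)
  expect_equal(sum(sub$n), nrow(co))
  expect_true(all(sub$converged))
  expect_error(fit_subgroups(co, "BC", "nope"), "not in cohort")
})

test_that("homogeneous effects give overlapping subgroup intervals", {
  co <- simulate_cohort(
    n = 8000, seed = 505,
    outcome_cfg = outcome_config(true_beta = c(BC = log(1.3)), seed = 506))
  sub <- fit_subgroups(co, "BC", "gender", model = 1)
  # same truth in both strata: intervals should overlap
  expect_gt(min(sub$ci_high), max(sub$ci_low))
})

test_that("heterogeneous subgroup effects are recovered in order", {
  # low-income slope twice the high-income slope
  co <- simulate_cohort(n = 12000, seed = 515,
                        outcome_cfg = outcome_config(
                          true_beta = c(BC = 0.2), seed = 516))
  eta <- 0.2 * co$BC * ifelse(co$income == "low", 2, 1)
  a <- -log(1 / 0.28143 - 1) - mean(eta)
  set.seed(517)
  co$high_risk <- rbinom(nrow(co), 1, plogis(a + eta))
  sub <- fit_subgroups(co, "BC", "income", model = 1)
  expect_gt(sub$beta[sub$stratum == "low"],
            sub$beta[sub$stratum == "high"])
  p <- interaction_test(co, "BC", "income", model = 1)
  expect_lt(as.numeric(p), 0.01)
})

test_that("interaction coefficient is zero for exactly homogeneous 2x2 strata", {
  # two strata with identical within-stratum odds ratios (cross-product 27/7)
  mk <- function(g) {
    d <- design_2x2(30, 70, 10, 90)
    data.frame(high_risk = d$y, x = d$X[, "exposure"], g = g)
  }
  co <- rbind(mk("a"), mk("b"))
  co$g <- factor(co$g)
  p <- interaction_test(co, "x", "g", model = 1)
  expect_equal(attr(p, "statistic"), 0, tolerance = 1e-8)
  expect_equal(as.numeric(p), 1, tolerance = 1e-6)
})

test_that("LRT and Wald interaction tests agree at large n for a binary stratifier", {
  co <- simulate_cohort(n = 20000, seed = 525,
                        outcome_cfg = outcome_config(
                          true_beta = c(BC = log(1.3)), seed = 526))
  p_lrt <- interaction_test(co, "BC", "gender", model = 2, method = "lrt")
  p_wald <- interaction_test(co, "BC", "gender", model = 2, method = "wald")
  expect_equal(attr(p_lrt, "df"), 1)
  expect_lt(abs(as.numeric(p_lrt) - as.numeric(p_wald)), 0.01)
})

test_that("interaction statistic is non-negative with p in (0, 1]", {
  co <- default_cohort()
  for (s in c("gender", "income")) {
    p <- interaction_test(co, "pm25", s, model = 2)
    expect_gte(attr(p, "statistic"), 0)
    expect_true(as.numeric(p) > 0 && as.numeric(p) <= 1)
    expect_equal(attr(p, "df"), nlevels(co[[s]]) - 1)
  }
})

test_that("stratified driver assembles the forest-plot table", {
  co <- default_cohort()
  tab <- run_stratified_analysis(co, pollutants = "BC",
                                 stratifiers = c("gender", "income"))
  expect_equal(nrow(tab), 5)  # 2 + 3 strata
  expect_true(all(c("stratum", "or", "interaction_p") %in% names(tab)))
  # interaction p shared across a stratifier's rows
  expect_equal(length(unique(tab$interaction_p[tab$stratifier == "income"])),
               1)
})

test_that("sensitivity windows reuse the same cohort and converge", {
  co <- default_cohort()[1:800, ]
  s_const <- generate_monthly_series(co, pollutants = c("pm25", "BC"),
                                     n_months = 120, trend = 0,
                                     season_amp = 0, noise_sd = 0, seed = 60)
  sens <- sensitivity_by_window(co, s_const, windows = c(3, 10),
                                pollutants = c("pm25", "BC"), model = 1)
  # constant series: identical exposures, hence identical odds ratios
  or3 <- sens$or[sens$window == 3]
  or10 <- sens$or[sens$window == 10]
  expect_equal(or10, or3, tolerance = 1e-10)
  # a trending series changes the exposures but all fits still converge
  s_tr <- generate_monthly_series(co, pollutants = c("pm25", "BC"),
                                  n_months = 120, trend = 0.05,
                                  season_amp = 0.1, noise_sd = 0.05,
                                  seed = 61)
  sens2 <- sensitivity_by_window(co, s_tr, windows = c(3, 5, 8, 10),
                                 pollutants = c("pm25", "BC"), model = 1)
  expect_true(all(sens2$converged))
  expect_equal(nrow(sens2), 8)
  expect_false(isTRUE(all.equal(sens2$or[sens2$window == 3],
                                sens2$or[sens2$window == 10])))
})
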