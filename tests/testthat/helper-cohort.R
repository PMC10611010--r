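# shared fixtures, built in code and memoized per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# mid-sized cohort under the default (residual-mass) study conditions
default_cohort <- function() {
  memo("default_cohort", function()
    simulate_cohort(n = 4000, seed = 101))
}

# exact-closure cohort with a two-constituent truth, for the ISM identities
closure_cohort <- function() {
  memo("closure_cohort", function()
    simulate_cohort(
      n = 3000, seed = 202,
      exposure_cfg = exposure_config(closure_mode = "exact_sum"),
      outcome_cfg = outcome_config(true_beta = c(BC = 0.4, SO4 = 0.1),
                                   seed = 303)))
}

# expand a 2x2 table (exposed cases/controls, unexposed cases/controls)
# into unit rows with an intercept + exposure design
design_2x2 <- function(a, b, c, d) {
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  x <- c(rep(1, a + b), rep(0, c + d))
  list(X = cbind("(Intercept)" = 1, exposure = x), y = y)
}
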