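#' Configuration of the covariate / risk-factor generator
#'
#' Default category probabilities and continuous moments reproduce the study
#' population's descriptive table: a rural Chinese cohort of 31,162 adults
#' aged 35-74. Categorical probabilities are stored as printed count / total
#' so each vector sums to one exactly.
#'
#' @param categorical named list of named probability vectors; names of each
#'   vector are the factor levels, first level = reference.
#' @param continuous named list of `c(mean, sd)` pairs (age yr, waist
#'   circumference cm, SBP and DBP mmHg, total and HDL cholesterol mg/dL).
#' @param binary named vector of prevalences in `[0, 1]` (coded 0/1).
#' @param age_range closed-open interval the age distribution is truncated to,
#'   matching the cohort's eligibility window.
#' @return An object of class `covariate_config`.
#' @export
covariate_config <- function(
    categorical = list(
      gender = c(female = 18999, male = 12163) / 31162,
      marital = c(married = 28558, single = 2604) / 31162,
      education = c(primary = 13920, junior = 13011, high = 4231) / 31162,
      income = c(low = 10993, mid = 10479, high = 9690) / 31162,
      smoking = c(never = 22727, former = 2323, current = 6112) / 31162,
      drinking = c(never = 24063, former = 1259, current = 5840) / 31162,
      physical_activity = c(low = 9360, moderate = 11887, high = 9915) / 31162,
      high_fat_diet = c(no = 25099, yes = 6063) / 31162,
      fruit_veg = c(no = 17941, yes = 13221) / 31162),
    continuous = list(
      age = c(mean = 55.898, sd = 9.782),
      wc = c(mean = 84.232, sd = 10.209),
      sbp = c(mean = 125.566, sd = 19.478),
      dbp = c(mean = 77.862, sd = 11.608),
      tc = c(mean = 184.676, sd = 37.361),
      hdl = c(mean = 51.287, sd = 12.891)),
    binary = c(diabetes = 2824, family_history = 4777, bp_treated = 4365) / 31162,
    age_range = c(35, 75)) {
  for (nm in names(categorical)) {
    p <- categorical[[nm]]
    if (abs(sum(p) - 1) > 1e-9)
      stop("probabilities for '", nm, "' sum to ", format(sum(p), digits = 12),
           ", not 1")
    if (any(p < 0)) stop("negative probability in '", nm, "'")
  }
  for (nm in names(continuous)) {
    if (continuous[[nm]][["sd"]] <= 0) stop("SD for '", nm, "' must be > 0")
  }
  if (any(binary < 0 | binary > 1)) stop("binary prevalences must be in [0, 1]")
  structure(list(categorical = categorical, continuous = continuous,
                 binary = binary, age_range = age_range),
            class = "covariate_config")
}

#' Sample the covariate / risk-factor block of a cohort
#'
#' Categorical variables are multinomial draws with levels in configured
#' order (first level is the modelling reference); age is normal truncated to
#' the eligibility window; other continuous risk factors are normal; binary
#' risk factors are Bernoulli 0/1.
#'
#' @param config a [covariate_config()].
#' @param n number of participants.
#' @param seed integer seed.
#' @return data.frame of factors, numerics, and 0/1 columns, no missing values.
#' @export
sample_covariates <- function(config, n, seed = 1L) {
  stopifnot(inherits(config, "covariate_config"), n >= 1)
  set.seed(seed)
  out <- list()
  for (nm in names(config$categorical)) {
    p <- config$categorical[[nm]]
    out[[nm]] <- factor(sample(names(p), n, replace = TRUE, prob = p),
                        levels = names(p))
  }
  for (nm in names(config$continuous)) {
    m <- config$continuous[[nm]][["mean"]]
    s <- config$continuous[[nm]][["sd"]]
    # age is truncated to the eligibility window; other risk factors are
    # floored at 0 (physiological positivity; a >3-sigma tail event)
    out[[nm]] <- if (nm == "age")
      qnorm_trunc(runif(n), m, s, config$age_range[1], config$age_range[2])
    else qnorm_trunc0(runif(n), m, s)
  }
  for (nm in names(config$binary)) {
    out[[nm]] <- rbinom(n, 1, config$binary[[nm]])
  }
  as.data.frame(out)
}
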