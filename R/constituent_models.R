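#' Constituent proportion of total PM2.5 mass
#'
#' `p_j = 100 * c_j / m`, in percent, so one unit of the regressor is one
#' percentage point of PM2.5 mass.
#'
#' @param c_j constituent concentration(s), ug/m3, >= 0.
#' @param m total PM2.5 mass(es), ug/m3, > 0.
#' @return proportion in percent.
#' @export
compute_proportion <- function(c_j, m) {
  if (any(m <= 0)) stop("total PM2.5 mass must be > 0")
  if (any(c_j < 0)) stop("constituent concentration must be >= 0")
  if (any(c_j > m))
    warning("constituent concentration exceeds total mass for ",
            sum(c_j > m), " value(s); proportion > 100%")
  100 * c_j / m
}

#' Total-mass-adjusted residual of a constituent
#'
#' Ordinary least squares of the constituent on total PM2.5 mass; the
#' residual `r_j = c_j - (a + b m)` carries the constituent's variation that
#' is orthogonal to total mass (zero mean, zero correlation with `m` by
#' construction).
#'
#' @param c_j constituent concentrations, ug/m3.
#' @param m total PM2.5 mass, same length (>= 3, non-constant).
#' @return residual vector, ug/m3.
#' @examples
#' compute_residual(c(1, 2, 4), c(1, 2, 3))  # 1/6, -1/3, 1/6
#' @export
compute_residual <- function(c_j, m) {
  if (length(c_j) != length(m)) stop("c_j and m must have equal length")
  if (length(m) < 3) stop("need at least 3 observations")
  if (var(m) == 0) stop("total mass is constant; residual slope undefined")
  as.numeric(residuals(lm(c_j ~ m)))
}

# one tidy row from a fit
result_row <- function(method, pollutant, model, fr) {
  data.frame(method = method, pollutant = pollutant, model = model,
             beta = fr$beta, se = fr$se, or = fr$or, ci_low = fr$ci_low,
             ci_high = fr$ci_high, n = fr$n, converged = fr$converged)
}

#' Constituent concentration analysis
#'
#' One single-pollutant logistic fit per pollutant (total PM2.5 and each
#' constituent separately), effect per 1 ug/m3, covariates per model.
#'
#' @param cohort cohort data.frame with outcome, covariates, and exposures.
#' @param model 1 (crude) or 2 (adjusted).
#' @param pollutants exposure columns to fit (default total + 6 constituents).
#' @param adjust_total if TRUE, each constituent model co-adjusts for total
#'   PM2.5 mass (off by default: single-pollutant reading).
#' @return tidy data.frame of rows (method, pollutant, model, beta, se, or,
#'   ci_low, ci_high, n, converged).
#' @export
run_concentration_analysis <- function(cohort, model = 2,
                                       pollutants = c("pm25", CONSTITUENTS),
                                       adjust_total = FALSE) {
  rows <- lapply(pollutants, function(p) {
    extra <- if (adjust_total && p != "pm25") "pm25" else character()
    fr <- fit_logistic(build_design(cohort, model_spec(p, model = model,
                                                       extra = extra)))
    result_row("concentration", p, model, fr)
  })
  do.call(rbind, rows)
}

#' Constituent proportion analysis
#'
#' Exposure is the constituent's share of total mass (percent, per
#' percentage point); the design additionally adjusts for total PM2.5 mass.
#'
#' @inheritParams run_concentration_analysis
#' @param constituents constituent columns.
#' @return tidy data.frame as in [run_concentration_analysis()].
#' @export
run_proportion_analysis <- function(cohort, model = 2,
                                    constituents = CONSTITUENTS) {
  rows <- lapply(constituents, function(p) {
    cohort$.prop <- compute_proportion(cohort[[p]], cohort$pm25)
    fr <- fit_logistic(build_design(cohort, model_spec(".prop", model = model,
                                                       extra = "pm25")))
    result_row("proportion", p, model, fr)
  })
  do.call(rbind, rows)
}

#' Constituent residual analysis
#'
#' Exposure is the total-mass-adjusted residual concentration (per 1 ug/m3);
#' total PM2.5 is not additionally included since the residual is orthogonal
#' to it by construction.
#'
#' @inheritParams run_proportion_analysis
#' @return tidy data.frame as in [run_concentration_analysis()].
#' @export
run_residual_analysis <- function(cohort, model = 2,
                                  constituents = CONSTITUENTS) {
  rows <- lapply(constituents, function(p) {
    cohort$.resid <- compute_residual(cohort[[p]], cohort$pm25)
    fr <- fit_logistic(build_design(cohort, model_spec(".resid",
                                                       model = model)))
    result_row("residual", p, model, fr)
  })
  do.call(rbind, rows)
}

#' Run all three constituent methods for the requested models
#'
#' @param cohort cohort data.frame.
#' @param models model set, subset of `c(1, 2)`.
#' @param adjust_total passed to [run_concentration_analysis()].
#' @return tidy data.frame; with both models, 38 rows
#'   (2 x (7 concentration + 6 proportion + 6 residual)).
#' @export
run_constituent_models <- function(cohort, models = c(1, 2),
                                   adjust_total = FALSE) {
  out <- lapply(models, function(m) rbind(
    run_concentration_analysis(cohort, model = m, adjust_total = adjust_total),
    run_proportion_analysis(cohort, model = m),
    run_residual_analysis(cohort, model = m)))
  do.call(rbind, out)
}
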