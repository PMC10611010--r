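#' Subgroup effect estimates for one pollutant and stratifier
#'
#' Independent adjusted fits within each stratum; the stratifier is removed
#' from its own stratum-specific covariate set (it is constant there).
#' Strata too small to support the model are skipped and recorded in
#' `attr(, "skipped")`.
#'
#' @param cohort cohort data.frame.
#' @param pollutant exposure column.
#' @param stratifier categorical cohort column with >= 2 levels.
#' @param model 1 or 2.
#' @return data.frame with one row per fitted stratum: `pollutant`,
#'   `stratifier`, `stratum`, `n`, `beta`, `se`, `or`, `ci_low`, `ci_high`,
#'   `converged`.
#' @export
fit_subgroups <- function(cohort, pollutant, stratifier, model = 2) {
  f <- cohort[[stratifier]]
  if (is.null(f)) stop("stratifier '", stratifier, "' not in cohort")
  if (!is.factor(f)) f <- factor(f)
  if (nlevels(f) < 2) stop("stratifier must have >= 2 levels")
  covs <- if (model == 2) setdiff(MODEL2_COVARIATES, stratifier)
          else character()
  rows <- list(); skipped <- character()
  for (lev in levels(f)) {
    sub <- cohort[which(f == lev), , drop = FALSE]
    spec <- model_spec(pollutant, model = model, covariates = covs)
    p_approx <- 2 + sum(vapply(covs, function(v)
      max(nlevels(factor(sub[[v]])) - 1, 1), numeric(1)))
    if (nrow(sub) <= p_approx + 1 || length(unique(sub$high_risk)) < 2) {
      skipped <- c(skipped, lev)
      next
    }
    fr <- fit_logistic(build_design(sub, spec))
    rows[[lev]] <- data.frame(pollutant = pollutant, stratifier = stratifier,
                              stratum = lev, n = fr$n, beta = fr$beta,
                              se = fr$se, or = fr$or, ci_low = fr$ci_low,
                              ci_high = fr$ci_high, converged = fr$converged)
  }
  if (length(skipped))
    message("skipped stratum(s) of ", stratifier, ": ",
            paste(skipped, collapse = ", "), " (too small)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Interaction test between exposure and a stratifier
#'
#' Compares the pooled adjusted model with and without exposure x stratifier
#' product terms. Default is the likelihood-ratio test with
#' `levels - 1` degrees of freedom; a Wald test on the product terms is
#' available as an option.
#'
#' @inheritParams fit_subgroups
#' @param method `"lrt"` (default) or `"wald"`.
#' @return the p-value, with `statistic`, `df` and `method` attributes.
#' @export
interaction_test <- function(cohort, pollutant, stratifier, model = 2,
                             method = c("lrt", "wald")) {
  method <- match.arg(method)
  spec <- model_spec(pollutant, model = model)
  if (model == 2 && !stratifier %in% spec$covariates)
    spec$covariates <- c(spec$covariates, stratifier)
  if (model == 1) spec$covariates <- stratifier
  vars <- unique(c(spec$outcome, pollutant, spec$covariates))
  d <- cohort[vars]
  d <- d[complete.cases(d), , drop = FALSE]
  y <- d[[spec$outcome]]
  rhs0 <- c(pollutant, spec$covariates)
  X0 <- model.matrix(reformulate(sprintf("`%s`", rhs0)), data = d)
  f1 <- reformulate(c(sprintf("`%s`", rhs0),
                      sprintf("`%s`:`%s`", pollutant, stratifier)))
  X1 <- model.matrix(f1, data = d)
  colnames(X0) <- gsub("`", "", colnames(X0), fixed = TRUE)
  colnames(X1) <- gsub("`", "", colnames(X1), fixed = TRUE)
  fit0 <- fit_logistic(X0, y, term = pollutant)
  fit1 <- fit_logistic(X1, y, term = pollutant)
  df <- ncol(X1) - ncol(X0)
  if (method == "lrt") {
    stat <- max(2 * (fit1$loglik - fit0$loglik), 0)
    p <- pchisq(stat, df = df, lower.tail = FALSE)
  } else {
    int_cols <- setdiff(colnames(X1), colnames(X0))
    b <- fit1$coefficients[int_cols]
    V <- fit1$vcov[int_cols, int_cols, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    p <- pchisq(stat, df = df, lower.tail = FALSE)
  }
  structure(p, statistic = stat, df = df, method = method)
}

#' Full stratified analysis over pollutants and stratifiers
#'
#' @param cohort cohort data.frame.
#' @param pollutants exposure columns.
#' @param stratifiers stratifier columns (default [STRATIFIERS]).
#' @param model 1 or 2.
#' @return forest-plot-ready data.frame: per-stratum estimates with the
#'   stratifier's interaction p-value repeated on its rows.
#' @export
run_stratified_analysis <- function(cohort,
                                    pollutants = c("pm25", CONSTITUENTS),
                                    stratifiers = STRATIFIERS, model = 2) {
  out <- list()
  for (p in pollutants) {
    for (s in stratifiers) {
      sub <- fit_subgroups(cohort, p, s, model = model)
      sub$interaction_p <- as.numeric(interaction_test(cohort, p, s,
                                                       model = model))
      out[[paste(p, s)]] <- sub
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multi-timescale exposure sensitivity analysis
#'
#' Recomputes each pollutant's long-term exposure as the 3-, 5-, 8- and
#' 10-year average of the monthly series, and refits the adjusted
#' concentration model per window. Participants without full monthly
#' coverage of a window are excluded from that window's fit (audited in the
#' `n_dropped` column).
#'
#' @param cohort cohort data.frame (outcome + covariates; exposure columns
#'   are replaced by the window averages).
#' @param series long monthly series from [generate_monthly_series()].
#' @param windows averaging windows in years.
#' @param pollutants pollutant columns present in the series.
#' @param model 1 or 2.
#' @return data.frame of rows (pollutant, window, beta, se, or, ci_low,
#'   ci_high, n, n_dropped, converged).
#' @export
sensitivity_by_window <- function(cohort, series, windows = c(3, 5, 8, 10),
                                  pollutants = c("pm25", CONSTITUENTS),
                                  model = 2) {
  out <- list()
  for (w in windows) {
    wa <- window_average(series, w, on_missing = "drop")
    nd <- attr(wa, "n_dropped")
    base <- cohort[!names(cohort) %in% pollutants]
    dw <- merge(base, wa, by = "id", sort = FALSE)
    for (p in pollutants) {
      fr <- fit_logistic(build_design(dw, model_spec(p, model = model)))
      out[[paste(p, w)]] <- data.frame(
        pollutant = p, window = w, beta = fr$beta, se = fr$se, or = fr$or,
        ci_low = fr$ci_low, ci_high = fr$ci_high, n = fr$n,
        n_dropped = nd, converged = fr$converged)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
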