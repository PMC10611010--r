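#' One leave-one-constituent-out substitution fit
#'
#' The isochronous substitution model: drop constituent `j`, keep total PM2.5
#' mass and the five other constituents in the design (plus covariates).
#' Because total mass is held fixed, the coefficient of a retained
#' constituent `k` estimates the effect of replacing 1 ug/m3 of `j` with
#' 1 ug/m3 of `k`; `OR_{j->k} = exp(beta_k)`.
#'
#' @param cohort cohort data.frame with all six constituents and `pm25`.
#' @param drop constituent to remove (the one being replaced).
#' @param model 1 or 2 (covariate set; 2 matches the published adjustments).
#' @return data.frame with one row per retained constituent: `drop`,
#'   `retain`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `kappa`, `n`,
#'   `converged`.
#' @export
fit_substitution_model <- function(cohort, drop, model = 2) {
  stopifnot(drop %in% CONSTITUENTS)
  retained <- setdiff(CONSTITUENTS, drop)
  spec <- model_spec(retained[1], model = model,
                     extra = c(retained[-1], "pm25"))
  des <- build_design(cohort, spec)
  fr <- fit_logistic(des)
  rows <- lapply(retained, function(k) {
    b <- unname(fr$coefficients[k]); s <- unname(fr$se_all[k])
    data.frame(drop = drop, retain = k, beta = b, se = s, or = exp(b),
               ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
               kappa = fr$kappa, n = fr$n, converged = fr$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fr
  out
}

#' Full substitution matrix over all ordered constituent pairs
#'
#' Runs the six leave-one-out fits and assembles the 30 ordered
#' (dropped, retained) substitution odds ratios.
#'
#' @inheritParams fit_substitution_model
#' @return long data.frame of 30 rows (class `substitution_matrix`),
#'   suitable for forest plots.
#' @export
substitution_matrix <- function(cohort, model = 2) {
  out <- do.call(rbind, lapply(CONSTITUENTS, function(j)
    fit_substitution_model(cohort, j, model = model)))
  rownames(out) <- NULL
  class(out) <- c("substitution_matrix", "data.frame")
  out
}

#' Reciprocity diagnostic of a substitution matrix
#'
#' Under exact mass closure the substitution algebra forces
#' `log OR_{j->k} = -log OR_{k->j}`; this returns the maximum absolute
#' log-sum over unordered pairs. Values near 0 confirm internal consistency;
#' with only approximate closure the deviation scales with the residual-mass
#' share.
#'
#' @param matrix a [substitution_matrix()].
#' @return maximum of `|log OR_{j->k} + log OR_{k->j}|` over unordered pairs.
#' @export
check_reciprocity <- function(matrix) {
  pairs <- utils::combn(CONSTITUENTS, 2)
  dev <- apply(pairs, 2, function(pr) {
    b_jk <- matrix$beta[matrix$drop == pr[1] & matrix$retain == pr[2]]
    b_kj <- matrix$beta[matrix$drop == pr[2] & matrix$retain == pr[1]]
    abs(b_jk + b_kj)
  })
  max(dev)
}
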