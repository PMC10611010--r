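#' Restricted cubic spline basis (truncated power form)
#'
#' For knots `t_1 < ... < t_K` returns `x` plus `K - 2` nonlinear terms
#'
#' `((x-t_j)_+^3 - (x-t_{K-1})_+^3 (t_K-t_j)/(t_K-t_{K-1})
#'   + (x-t_K)_+^3 (t_{K-1}-t_j)/(t_K-t_{K-1})) / (t_K-t_1)^2`,
#'
#' which is linear (zero second derivative) below the first and above the
#' last knot.
#'
#' @param x numeric vector.
#' @param knots strictly increasing knot locations, K in 3..5.
#' @return matrix with columns `lin`, `nl1` ... `nl(K-2)`.
#' @export
rcs_basis <- function(x, knots) {
  K <- length(knots)
  if (K < 3 || K > 5) stop("number of knots must be 3, 4, or 5")
  if (any(diff(knots) <= 0))
    stop("knots must be strictly increasing (no duplicates)")
  cube <- function(u) pmax(u, 0)^3
  tK <- knots[K]; tK1 <- knots[K - 1]
  norm <- (tK - knots[1])^2
  nl <- vapply(seq_len(K - 2), function(j) {
    tj <- knots[j]
    (cube(x - tj) -
       cube(x - tK1) * (tK - tj) / (tK - tK1) +
       cube(x - tK) * (tK1 - tj) / (tK - tK1)) / norm
  }, numeric(length(x)))
  if (length(x) == 1) nl <- matrix(nl, nrow = 1)
  out <- cbind(lin = x, nl)
  colnames(out) <- c("lin", paste0("nl", seq_len(K - 2)))
  out
}

#' Default knot placement
#'
#' Sample quantiles at the conventional positions: (0.10, 0.50, 0.90) for
#' K = 3, (0.05, 0.35, 0.65, 0.95) for K = 4, (0.05, 0.275, 0.50, 0.725,
#' 0.95) for K = 5.
#'
#' @param x exposure values.
#' @param K number of knots (3-5).
#' @return numeric vector of knot locations.
#' @export
rcs_knots <- function(x, K = 4) {
  probs <- switch(as.character(K),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stop("K must be 3, 4, or 5"))
  unname(quantile(x, probs))
}

#' Restricted-cubic-spline exposure-response curve
#'
#' Fits a logistic model with an RCS expansion of the exposure (plus model
#' covariates), and returns the odds-ratio curve relative to a reference
#' exposure, with pointwise Wald confidence bands from the coefficient
#' covariance, and a likelihood-ratio test of the nonlinear terms.
#'
#' @param cohort cohort data.frame.
#' @param pollutant exposure column.
#' @param model 1 or 2.
#' @param K number of knots (default 4).
#' @param x_ref reference exposure; default sample median (OR there is 1).
#' @param n_grid grid size between the 1st and 99th exposure percentiles.
#' @param knots optional explicit knot locations (overrides `K` placement).
#' @return Object of class `spline_curve`: `pollutant`, `knots`, `x_ref`,
#'   `curve` (data.frame x, or, ci_low, ci_high), `p_nonlinear`, `fit`.
#' @export
fit_spline_curve <- function(cohort, pollutant, model = 2, K = 4,
                             x_ref = NULL, n_grid = 100, knots = NULL) {
  spec <- model_spec(pollutant, model = model)
  vars <- c(spec$outcome, pollutant, spec$covariates)
  miss <- setdiff(vars, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  d <- cohort[vars]
  d <- d[complete.cases(d), , drop = FALSE]
  x <- d[[pollutant]]
  if (is.null(knots)) knots <- rcs_knots(x, K)
  K <- length(knots)
  if (is.null(x_ref)) x_ref <- median(x)
  B <- rcs_basis(x, knots)
  colnames(B) <- paste0(".rcs", seq_len(ncol(B)))
  dd <- cbind(d, B)
  rhs <- c(colnames(B), spec$covariates)
  X <- model.matrix(reformulate(sprintf("`%s`", rhs)), data = dd)
  colnames(X) <- gsub("`", "", colnames(X), fixed = TRUE)
  y <- d[[spec$outcome]]
  fit <- fit_logistic(X, y, term = ".rcs1")
  # linear-only reduced fit for the nonlinearity LRT (K - 2 df)
  Xlin <- X[, !colnames(X) %in% paste0(".rcs", 2:ncol(B)), drop = FALSE]
  fit_lin <- fit_logistic(Xlin, y, term = ".rcs1")
  lrt <- 2 * (fit$loglik - fit_lin$loglik)
  p_nl <- pchisq(max(lrt, 0), df = K - 2, lower.tail = FALSE)
  grid <- seq(quantile(x, 0.01), quantile(x, 0.99), length.out = n_grid)
  Bg <- rcs_basis(grid, knots)
  Br <- rcs_basis(x_ref, knots)
  spl_cols <- paste0(".rcs", seq_len(ncol(B)))
  idx <- match(spl_cols, colnames(X))
  beta_s <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  D <- sweep(Bg, 2, as.numeric(Br))
  log_or <- drop(D %*% beta_s)
  se <- sqrt(rowSums((D %*% V) * D))
  curve <- data.frame(x = grid, or = exp(log_or),
                      ci_low = exp(log_or - 1.96 * se),
                      ci_high = exp(log_or + 1.96 * se))
  structure(list(pollutant = pollutant, knots = knots, x_ref = x_ref,
                 curve = curve, p_nonlinear = p_nl, fit = fit,
                 fit_linear = fit_lin),
            class = "spline_curve")
}

#' @export
print.spline_curve <- function(x, ...) {
  cat(sprintf(
    "RCS exposure-response for %s: %d knots, reference %.3f, nonlinearity p = %.4g\n",
    x$pollutant, length(x$knots), x$x_ref, x$p_nonlinear))
  invisible(x)
}

#' Odds ratio at arbitrary exposures from a fitted spline curve
#'
#' @param object a `spline_curve`.
#' @param x exposures to evaluate at.
#' @return data.frame (x, or, ci_low, ci_high) relative to the curve's
#'   reference exposure.
#' @export
predict_spline_or <- function(object, x) {
  stopifnot(inherits(object, "spline_curve"))
  B <- rcs_basis(x, object$knots)
  Br <- rcs_basis(object$x_ref, object$knots)
  spl_cols <- paste0(".rcs", seq_len(ncol(B)))
  idx <- match(spl_cols, names(object$fit$coefficients))
  beta_s <- object$fit$coefficients[idx]
  V <- object$fit$vcov[idx, idx, drop = FALSE]
  D <- sweep(B, 2, as.numeric(Br))
  log_or <- drop(D %*% beta_s)
  se <- sqrt(rowSums((D %*% V) * D))
  data.frame(x = x, or = exp(log_or), ci_low = exp(log_or - 1.96 * se),
             ci_high = exp(log_or + 1.96 * se))
}
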