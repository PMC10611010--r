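#' Specify a single-exposure logistic model
#'
#' @param exposure name of the exposure column (numeric, per-unit effect).
#' @param model 1 (unadjusted) or 2 (adjusted for [MODEL2_COVARIATES]).
#' @param outcome binary outcome column name.
#' @param extra additional numeric adjustment columns placed directly after
#'   the exposure (e.g. total PM2.5 mass in proportion models, the retained
#'   constituents in substitution models).
#' @param covariates explicit covariate override; default follows `model`.
#' @param scale multiply the exposure by this factor before fitting (effects
#'   are then per `1/scale` original units); default 1 (per unit).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(exposure, model = 2, outcome = "high_risk",
                       extra = character(), covariates = NULL, scale = 1) {
  stopifnot(model %in% c(1, 2))
  if (is.null(covariates))
    covariates <- if (model == 2) MODEL2_COVARIATES else character()
  structure(list(exposure = exposure, model = model, outcome = outcome,
                 extra = extra, covariates = covariates, scale = scale),
            class = "model_spec")
}

#' Build the design matrix and response for a model specification
#'
#' Complete-case rows only; categorical covariates are dummy-encoded against
#' their first factor level; an intercept is always included.
#'
#' @param cohort cohort data.frame.
#' @param spec a [model_spec()].
#' @return list with `X` (design matrix), `y` (0/1 response), `n`, and
#'   `exposure` (the exposure column's name in `X`).
#' @export
build_design <- function(cohort, spec) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- c(spec$outcome, spec$exposure, spec$extra, spec$covariates)
  miss <- setdiff(vars, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  d <- cohort[vars]
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) == 0) stop("no complete cases for the requested model")
  y <- d[[spec$outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome '", spec$outcome, "' must be 0/1")
  rhs <- c(spec$exposure, spec$extra, spec$covariates)
  X <- model.matrix(reformulate(sprintf("`%s`", rhs)), data = d)
  colnames(X)[1] <- "(Intercept)"
  colnames(X) <- gsub("`", "", colnames(X), fixed = TRUE)
  if (spec$scale != 1) X[, spec$exposure] <- X[, spec$exposure] * spec$scale
  const <- apply(X[, -1, drop = FALSE], 2, function(col) all(col == col[1]))
  if (any(const))
    warning("constant column(s) in design: ",
            paste(names(const)[const], collapse = ", "))
  list(X = X, y = as.numeric(y), n = nrow(X), exposure = spec$exposure,
       spec = spec)
}

# negative log-likelihood, numerically stable
logistic_nll <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  -sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
}

#' Fit a logistic regression by maximum likelihood
#'
#' Fits via iteratively reweighted least squares (`stats::glm.fit`) and then
#' polishes with a few Newton steps until the score norm is below 1e-10, so
#' downstream algebraic identities (the substitution-model reparameterization)
#' hold to tight tolerance. Rank-deficient designs are an error; separation
#' (fitted probabilities pinned at 0/1 with runaway coefficients) is flagged,
#' never silent.
#'
#' @param design design matrix with intercept, or the list from
#'   [build_design()].
#' @param response 0/1 response (ignored when `design` is a build_design list).
#' @param term name of the exposure column the headline estimate is for;
#'   defaults to the second column.
#' @return Object of class `fit_result`: `beta`, `se`, `or`, `ci_low`,
#'   `ci_high` (Wald, z = 1.96) for `term`; plus `coefficients`, `se_all`,
#'   `vcov`, `loglik`, `n`, `kappa` (design condition number), `converged`,
#'   `separation`, and `grad_norm`.
#' @export
fit_logistic <- function(design, response = NULL, term = NULL) {
  if (is.list(design) && !is.null(design$X)) {
    X <- design$X; y <- design$y
    if (is.null(term)) term <- design$exposure
  } else {
    X <- as.matrix(design); y <- as.numeric(response)
  }
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  if (is.null(term)) term <- colnames(X)[min(2, ncol(X))]
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; drop aliased columns")
  if (nrow(X) <= ncol(X))
    stop("more parameters than observations")
  cn <- kappa(X)
  if (cn > 1e8)
    warning(sprintf("design is near-collinear (condition number %.3g)", cn))
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-12, maxit = 100)))
  beta <- fit$coefficients
  # Newton polish: drive the score to ~0 so MLE identities hold tightly
  grad_norm <- Inf
  H <- NULL
  separation <- FALSE
  for (it in 1:40) {
    p <- plogis(drop(X %*% beta))
    g <- crossprod(X, y - p)
    grad_norm <- max(abs(g))
    w <- pmax(p * (1 - p), 1e-14)
    H <- crossprod(X, X * w)
    if (any(pmin(p, 1 - p) < 1e-12) && max(abs(beta)) > 12) {
      separation <- TRUE
      break
    }
    if (grad_norm < 1e-10) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # halve the step if it does not improve the likelihood
    nll0 <- logistic_nll(beta, X, y)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      if (logistic_nll(cand, X, y) <= nll0 + 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * drop(step)
  }
  p <- plogis(drop(X %*% beta))
  loglik <- sum(dbinom(y, 1, p, log = TRUE))
  vc <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(vc) <- list(colnames(X), colnames(X))
  se_all <- sqrt(diag(vc))
  converged <- is.finite(grad_norm) && grad_norm < 1e-8 && !separation
  if (!converged)
    warning("logistic fit did not converge cleanly",
            if (separation) " (separation detected: fitted probabilities pinned at 0/1)")
  if (!term %in% colnames(X)) stop("term '", term, "' not in design")
  b <- unname(beta[term]); s <- unname(se_all[term])
  structure(list(term = term, beta = b, se = s, or = exp(b),
                 ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
                 n = nrow(X), loglik = loglik, kappa = cn,
                 converged = converged, separation = separation,
                 grad_norm = grad_norm,
                 coefficients = beta, se_all = se_all, vcov = vc),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("logistic fit (n = %d): %s OR %.3f (%.3f, %.3f)%s\n",
              x$n, x$term, x$or, x$ci_low, x$ci_high,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
as.data.frame.fit_result <- function(x, ...) {
  data.frame(term = x$term, beta = x$beta, se = x$se, or = x$or,
             ci_low = x$ci_low, ci_high = x$ci_high, n = x$n,
             loglik = x$loglik, kappa = x$kappa, converged = x$converged)
}

#' Percent excess risk implied by an odds ratio
#'
#' `(OR - 1) * 100`, reported to one decimal (half-up) — the "x% higher risk
#' per unit" phrasing.
#'
#' @param or odds ratio(s), > 0.
#' @return percent excess, one decimal.
#' @examples
#' percent_excess(1.493)  # 49.3
#' @export
percent_excess <- function(or) {
  if (any(or <= 0)) stop("OR must be > 0")
  round_half_up((or - 1) * 100, 1)
}

#' Independent small-instance likelihood maximizer (test oracle)
#'
#' Maximizes the same Bernoulli likelihood as [fit_logistic()] by
#' derivative-free search (golden-section in 1D; Nelder-Mead restarts plus a
#' quasi-Newton polish on numerical gradients otherwise). Restricted to tiny
#' instances; used by the test suite to cross-check the production fitter.
#'
#' @param X design matrix, <= 30 rows and <= 4 columns.
#' @param y 0/1 response.
#' @return list with `coefficients` and `separation` flag.
#' @export
oracle_fit <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) > 30 || ncol(X) > 4)
    stop("oracle_fit is restricted to <= 30 rows and <= 4 columns")
  nll <- function(b) {
    v <- logistic_nll(b, X, y)
    if (!is.finite(v)) 1e10 else v  # keep searches away from overflow
  }
  k <- ncol(X)
  if (k == 1) {
    opt <- optimize(function(b) nll(b), c(-25, 25), tol = 1e-14)
    beta <- opt$minimum
  } else {
    beta <- rep(0, k)
    for (r in 1:3) {
      o <- optim(beta, nll, method = "Nelder-Mead",
                 control = list(maxit = 10000, reltol = 1e-15))
      beta <- o$par
    }
    # cyclic golden-section refinement, one coordinate at a time
    for (sweep in 1:500) {
      delta <- 0
      for (j in seq_len(k)) {
        opt <- optimize(function(t) {
          bb <- beta; bb[j] <- t; nll(bb)
        }, interval = c(beta[j] - 1, beta[j] + 1), tol = 1e-12)
        delta <- max(delta, abs(opt$minimum - beta[j]))
        beta[j] <- opt$minimum
      }
      if (delta < 1e-10) break
    }
  }
  p <- plogis(drop(X %*% beta))
  separation <- any(pmin(p, 1 - p) < 1e-10) && max(abs(beta)) > 12
  if (separation)
    warning("separation detected: fitted probabilities pinned at 0/1")
  list(coefficients = setNames(as.numeric(beta),
                               colnames(X) %||% paste0("x", seq_len(k))),
       separation = separation)
}
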