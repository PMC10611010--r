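#' Build a Cox-score risk coefficient table
#'
#' The 10-year risk engine is table-driven: a sex-specific list of terms
#' (name, variables, transform, coefficient, cohort mean of the transformed
#' term) plus a baseline 10-year survival S0. Predicted risk is
#' `1 - S0^exp(LP - LPbar)` with `LPbar = sum(coef * mean)`. The published
#' China-PAR coefficients are not shipped (they are not printed in the source
#' this package accompanies); users supply them via this schema, and a
#' clearly-synthetic example table is provided for testing
#' ([example_risk_table()]).
#'
#' Transforms: `identity`, `log`, `indicator` (for `indicator`, a variable
#' written `"column=level"` is the 0/1 indicator of that factor level; a bare
#' column must already be 0/1). A term with two variables is their product
#' (interaction) after transformation.
#'
#' @param sex label ("female", "male", or "any").
#' @param terms data.frame with columns `term` (unique names), `variables`
#'   (one or two field names separated by `*`), `transform`, `coef`, `mean`.
#' @param S0 baseline 10-year survival, in (0, 1).
#' @return Object of class `risk_table`.
#' @export
risk_coefficient_table <- function(sex, terms, S0) {
  terms <- as.data.frame(terms)
  req <- c("term", "variables", "transform", "coef", "mean")
  if (!all(req %in% names(terms)))
    stop("terms must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(terms$term)) stop("term names must be unique")
  bad <- setdiff(terms$transform, c("identity", "log", "indicator"))
  if (length(bad)) stop("unknown transform(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(S0) || length(S0) != 1 || S0 <= 0 || S0 >= 1)
    stop("S0 must be a single value in (0, 1); got ", S0)
  structure(list(sex = sex, terms = terms, S0 = S0,
                 lp_bar = sum(terms$coef * terms$mean)),
            class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  cat("Cox-score risk coefficient table (sex: ", x$sex, ", S0 = ", x$S0,
      ", ", nrow(x$terms), " terms)\n", sep = "")
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Load a risk coefficient table from a JSON file
#'
#' Expected layout: `{"version": ..., "tables": [{"sex": ..., "S0": ...,
#' "terms": [{"term", "variables", "transform", "coef", "mean"}, ...]}, ...]}`.
#'
#' @param path JSON file path.
#' @return A named list of `risk_table` objects, keyed by sex.
#' @export
load_risk_table <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tabs <- raw$tables
  out <- list()
  for (i in seq_len(nrow(tabs))) {
    terms <- tabs$terms[[i]]
    out[[tabs$sex[i]]] <- risk_coefficient_table(tabs$sex[i], terms,
                                                 tabs$S0[i])
  }
  out
}

#' Synthetic example risk coefficient table
#'
#' A plausible but entirely synthetic Cox-score table over the predictors the
#' 10-year ASCVD score uses (age, waist circumference, SBP with treatment,
#' cholesterol, HDL-C, smoking, diabetes, family history). It exists so the
#' engine and the `chinapar` outcome mechanism are testable; it is NOT the
#' published China-PAR equation.
#'
#' @return Named list of two `risk_table` objects (`female`, `male`).
#' @export
example_risk_table <- function() {
  load_risk_table(system.file("extdata", "synthetic_risk_coefficients.json",
                              package = "pm25ascvd", mustWork = TRUE))
}

# evaluate one term for a batch of records
eval_term <- function(records, variables, transform) {
  vars <- strsplit(variables, "*", fixed = TRUE)[[1]]
  vars <- trimws(vars)
  v <- rep(1, nrow(records))
  for (vn in vars) {
    if (grepl("=", vn, fixed = TRUE)) {
      parts <- trimws(strsplit(vn, "=", fixed = TRUE)[[1]])
      if (!parts[1] %in% names(records))
        stop("required field '", parts[1], "' is missing")
      x <- as.numeric(records[[parts[1]]] == parts[2])
    } else {
      if (!vn %in% names(records))
        stop("required field '", vn, "' is missing")
      x <- records[[vn]]
      if (!is.numeric(x)) stop("field '", vn, "' must be numeric")
    }
    x <- switch(transform,
                identity = x,
                log = {
                  if (any(x <= 0)) stop("log transform of non-positive '",
                                        vn, "'")
                  log(x)
                },
                indicator = {
                  if (!all(x %in% c(0, 1)))
                    stop("indicator term '", vn, "' is not 0/1")
                  x
                })
    v <- v * x
  }
  v
}

#' Linear predictor of the risk score
#'
#' `LP = sum_i coef_i * g_i(x_i)` over the table's terms.
#'
#' @param records data.frame of risk-factor fields (one row per participant).
#' @param table a [risk_coefficient_table()].
#' @return numeric vector of linear predictors.
#' @export
linear_predictor <- function(records, table) {
  stopifnot(inherits(table, "risk_table"))
  if (table$sex %in% c("female", "male") && "gender" %in% names(records)) {
    if (any(records$gender != table$sex))
      stop("records contain sex '",
           paste(unique(records$gender[records$gender != table$sex]),
                 collapse = ", "),
           "' but table is for '", table$sex, "'")
  }
  lp <- rep(0, nrow(records))
  for (i in seq_len(nrow(table$terms))) {
    lp <- lp + table$terms$coef[i] *
      eval_term(records, table$terms$variables[i], table$terms$transform[i])
  }
  lp
}

#' Predicted 10-year risk from a linear predictor
#'
#' `risk = 1 - S0^exp(LP - LPbar)`, strictly increasing in LP and in (0, 1)
#' for finite LP.
#'
#' @param lp numeric vector of linear predictors.
#' @param table a [risk_coefficient_table()] (supplies S0 and LPbar).
#' @return data.frame with `lp`, `risk`, `high_risk` (risk >= 10%).
#' @export
ten_year_risk <- function(lp, table) {
  stopifnot(inherits(table, "risk_table"))
  risk <- 1 - table$S0^exp(lp - table$lp_bar)
  data.frame(lp = lp, risk = risk,
             high_risk = as.integer(risk >= 0.10))
}

#' Classify predicted 10-year risk at the 10% threshold
#'
#' High risk iff risk >= 10% (boundary inclusive on the high side).
#'
#' @param risk numeric vector of predicted risks in [0, 1].
#' @return factor with levels `low`, `high`.
#' @export
classify_risk <- function(risk) {
  if (any(!is.finite(risk)) || any(risk < 0 | risk > 1))
    stop("risk must be in [0, 1]")
  factor(ifelse(risk >= 0.10, "high", "low"), levels = c("low", "high"))
}

#' Score a cohort with sex-specific risk tables
#'
#' @param cohort cohort data.frame; rows are matched to tables by the
#'   `gender` column when the tables are sex-specific.
#' @param tables a single `risk_table` or a named list keyed by sex.
#' @return data.frame (`id` if present, `lp`, `risk`, `high_risk`), row order
#'   matching `cohort`.
#' @export
score_cohort <- function(cohort, tables) {
  if (inherits(tables, "risk_table")) tables <- list(any = tables)
  out <- data.frame(lp = rep(NA_real_, nrow(cohort)),
                    risk = NA_real_, high_risk = NA_integer_)
  if (identical(names(tables), "any")) {
    rr <- ten_year_risk(linear_predictor(cohort, tables$any), tables$any)
    out[] <- rr
  } else {
    for (sx in names(tables)) {
      rows <- which(cohort$gender == sx)
      if (!length(rows)) next
      rr <- ten_year_risk(linear_predictor(cohort[rows, , drop = FALSE],
                                           tables[[sx]]), tables[[sx]])
      out[rows, ] <- rr
    }
    if (anyNA(out$risk))
      stop("no risk table for sex: ",
           paste(unique(cohort$gender[is.na(out$risk)]), collapse = ", "))
  }
  if ("id" %in% names(cohort)) out <- cbind(id = cohort$id, out)
  out
}
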