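#' Apply the enrolment exclusion cascade
#'
#' Sequential bookkeeping of the cohort filter: participants with missing
#' risk-score predictors, outside the 35-74 age window, or with prior ASCVD
#' are removed in that order, and every step is audited.
#'
#' @param n0 enrolled count.
#' @param missing excluded for missing 10-year risk predictors.
#' @param age_out excluded for age <35 or >=75 years.
#' @param prior_ascvd excluded for ASCVD history.
#' @return list with `remaining` (final analysed count) and `audit`, a
#'   data.frame of (step, excluded, remaining) rows.
#' @examples
#' apply_exclusions(39259, 476, 3537, 4084)$remaining
#' @export
apply_exclusions <- function(n0, missing, age_out, prior_ascvd) {
  counts <- c(n0 = n0, missing = missing, age_out = age_out,
              prior_ascvd = prior_ascvd)
  if (any(counts < 0)) stop("all counts must be >= 0")
  steps <- c("missing risk predictors" = missing,
             "age <35 or >=75 years" = age_out,
             "prior ASCVD" = prior_ascvd)
  remaining <- n0
  audit <- data.frame(step = c("enrolled", names(steps)),
                      excluded = c(0, unname(steps)),
                      remaining = NA_real_)
  audit$remaining[1] <- remaining
  for (i in seq_along(steps)) {
    remaining <- remaining - steps[[i]]
    if (remaining < 0)
      stop("exclusion step '", names(steps)[i],
           "' leaves a negative count (", remaining, ")")
    audit$remaining[i + 1] <- remaining
  }
  list(remaining = remaining, audit = audit)
}
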