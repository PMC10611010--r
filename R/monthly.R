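#' Generate per-participant monthly exposure series
#'
#' Expands a cohort's cross-sectional exposures into monthly time series for
#' the multi-timescale sensitivity analysis: each participant/pollutant value
#' is modulated by an optional linear trend, a 12-month seasonal cycle, and
#' multiplicative noise, then floored at zero. With `trend`, `season_amp` and
#' `noise_sd` all zero the series is constant at the cross-sectional value.
#'
#' @param cohort cohort data.frame with an `id` column and pollutant columns.
#' @param pollutants pollutant columns to expand.
#' @param n_months number of months ending the month before `baseline_date`.
#' @param baseline_date baseline investigation date (`Date` or "YYYY-MM-DD").
#' @param trend relative change per year (e.g. 0.02 = +2%/yr toward baseline).
#' @param season_amp relative amplitude of the seasonal cosine.
#' @param noise_sd relative SD of the multiplicative month-to-month noise.
#' @param seed integer seed.
#' @return Long data.frame (id, pollutant, year, month, value) with the
#'   baseline date in `attr(, "baseline_date")`; values >= 0, months strictly
#'   increasing within each id x pollutant.
#' @export
generate_monthly_series <- function(cohort,
                                    pollutants = c("pm25", CONSTITUENTS),
                                    n_months = 120,
                                    baseline_date = as.Date("2016-07-01"),
                                    trend = 0, season_amp = 0.1,
                                    noise_sd = 0.05, seed = 1L) {
  stopifnot("id" %in% names(cohort), all(pollutants %in% names(cohort)))
  baseline_date <- as.Date(baseline_date)
  set.seed(seed)
  b <- month_index(baseline_date)
  idx <- (b - n_months):(b - 1)         # ends the month before baseline
  years <- idx %/% 12
  months <- idx %% 12 + 1
  n <- nrow(cohort)
  t_rel <- (idx - (b - 1)) / 12         # years before baseline (<= 0)
  season <- season_amp * cos(2 * pi * months / 12)
  out <- vector("list", length(pollutants))
  for (k in seq_along(pollutants)) {
    base <- cohort[[pollutants[k]]]
    # participants x months
    mod <- outer(rep(1, n), 1 + trend * t_rel + season)
    noise <- if (noise_sd > 0)
      matrix(rnorm(n * n_months, 0, noise_sd), n, n_months) else 0
    vals <- pmax(base * (mod + noise), 0)
    out[[k]] <- data.frame(
      id = rep(cohort$id, each = n_months),
      pollutant = pollutants[k],
      year = rep(years, times = n),
      month = rep(months, times = n),
      value = as.vector(t(vals)))
  }
  series <- do.call(rbind, out)
  attr(series, "baseline_date") <- baseline_date
  series
}

# months since year 0 (January of year y = y*12)
month_index <- function(x) {
  if (inherits(x, "Date")) {
    lt <- as.POSIXlt(x)
    lt$year * 12L + 1900L * 12L + lt$mon
  } else {
    stop("expected a Date")
  }
}

fmt_month <- function(idx) sprintf("%04d-%02d", idx %/% 12, idx %% 12 + 1)

#' Multi-year average of monthly exposure series
#'
#' Arithmetic mean of exactly `years` x 12 monthly values per participant and
#' pollutant, ending with the month before the baseline month (the baseline
#' month itself is excluded, as exposure accrues prior to the baseline
#' investigation).
#'
#' @param series long data.frame (id, pollutant, year, month, value), e.g.
#'   from [generate_monthly_series()].
#' @param years averaging window in years; one of 3, 5, 8, 10.
#' @param baseline_date baseline date; defaults to the series attribute.
#' @param on_missing `"error"` stops at the first participant/pollutant with
#'   incomplete coverage, naming the first missing month; `"drop"` excludes
#'   such participants and records them in `attr(, "n_dropped")`.
#' @return Wide data.frame: `id` plus one column of window means per
#'   pollutant (ug/m3).
#' @export
window_average <- function(series, years,
                           baseline_date = attr(series, "baseline_date"),
                           on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  if (!years %in% c(3, 5, 8, 10))
    stop("years must be one of 3, 5, 8, 10")
  if (is.null(baseline_date)) stop("baseline_date is required")
  b <- month_index(as.Date(baseline_date))
  need <- (b - 12 * years):(b - 1)
  idx <- series$year * 12L + (series$month - 1L)
  keep <- idx >= need[1] & idx <= need[length(need)]
  s <- series[keep, , drop = FALSE]
  s_idx <- idx[keep]
  key <- paste(s$id, s$pollutant, sep = "\r")
  if (anyDuplicated(paste(key, s_idx, sep = "\r")))
    stop("duplicate months in series: months must be strictly increasing")
  cnt <- tapply(s_idx, key, length)
  ids_all <- unique(series$id)
  pols <- unique(series$pollutant)
  full_keys <- as.vector(outer(ids_all, pols, paste, sep = "\r"))
  short <- full_keys[is.na(cnt[full_keys]) | cnt[full_keys] < 12 * years]
  dropped_ids <- integer(0)
  if (length(short)) {
    first <- strsplit(short[1], "\r")[[1]]
    have <- s_idx[key == short[1]]
    miss <- setdiff(need, have)[1]
    if (on_missing == "error")
      stop("insufficient monthly coverage for id ", first[1], ", pollutant ",
           first[2], ": first missing month is ", fmt_month(miss))
    dropped_ids <- unique(as.integer(vapply(strsplit(short, "\r"),
                                            `[`, "", 1)))
    s <- s[!s$id %in% dropped_ids, , drop = FALSE]
    key <- paste(s$id, s$pollutant, sep = "\r")
  }
  means <- tapply(s$value, list(factor(s$id, levels = setdiff(ids_all, dropped_ids)),
                                factor(s$pollutant, levels = pols)), mean)
  out <- data.frame(id = as.integer(rownames(means)))
  for (p in pols) out[[p]] <- as.numeric(means[, p])
  attr(out, "n_dropped") <- length(dropped_ids)
  out
}
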