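#' Descriptive summary table of a cohort
#'
#' Mean (+/- SD) for continuous variables, n (%) for categorical and binary
#' ones, percentages to 3 decimals (half-up), in the layout of a standard
#' baseline-characteristics table.
#'
#' @param cohort cohort data.frame.
#' @param continuous,categorical,binary column sets; defaults cover the
#'   standard cohort schema, silently skipping absent columns.
#' @return data.frame with columns `variable`, `level`, `summary`.
#' @export
summarize_table1 <- function(cohort,
                             continuous = c("age", "wc", "sbp", "dbp", "tc",
                                            "hdl"),
                             categorical = c("gender", "marital", "education",
                                             "income", "smoking", "drinking",
                                             "physical_activity",
                                             "high_fat_diet", "fruit_veg"),
                             binary = c("diabetes", "family_history",
                                        "bp_treated", "high_risk")) {
  n <- nrow(cohort)
  if (n == 1) warning("single-row cohort: SDs reported as 0")
  rows <- list()
  add <- function(variable, level, summary)
    rows[[length(rows) + 1]] <<- data.frame(variable = variable,
                                            level = level, summary = summary)
  for (v in intersect(continuous, names(cohort))) {
    s <- if (n == 1) 0 else sd(cohort[[v]])
    add(v, "", paste0(fmt_num(mean(cohort[[v]]), 3), " ± ",
                      fmt_num(s, 3)))
  }
  for (v in intersect(categorical, names(cohort))) {
    f <- factor(cohort[[v]])
    for (lev in levels(f)) {
      k <- sum(f == lev)
      add(v, lev, paste0(k, " (", fmt_num(100 * k / n, 3), ")"))
    }
  }
  for (v in intersect(binary, names(cohort))) {
    k <- sum(cohort[[v]] == 1)
    add(v, "yes", paste0(k, " (", fmt_num(100 * k / n, 3), ")"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a pipeline configuration
#'
#' @param n cohort size to simulate.
#' @param seed master seed; every stage derives a named substream from it.
#' @param stages stages to run, in order, from: simulate, score,
#'   concentration, proportion, residual, ism, spline, stratify, sensitivity,
#'   report.
#' @param models model set (subset of 1:2).
#' @param out_dir output directory for stage CSVs and the run manifest.
#' @param pollutants exposure columns analysed.
#' @param cohort optional pre-built cohort data.frame (skips `simulate`).
#' @param digits rounding for the report stage (default 3, table style).
#' @return list of class `pipeline_config`, validated fail-fast.
#' @export
pipeline_config <- function(n = 31162, seed = 1L,
                            stages = c("simulate", "score", "concentration",
                                       "proportion", "residual", "ism",
                                       "spline", "stratify", "sensitivity",
                                       "report"),
                            models = c(1, 2), out_dir = tempdir(),
                            pollutants = c("pm25", CONSTITUENTS),
                            cohort = NULL, digits = 3) {
  known <- c("simulate", "score", "concentration", "proportion", "residual",
             "ism", "spline", "stratify", "sensitivity", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!all(models %in% c(1, 2))) stop("models must be a subset of c(1, 2)")
  needs_cohort <- setdiff(stages, "simulate")
  if (length(needs_cohort) && !"simulate" %in% stages && is.null(cohort))
    stop("stages ", paste(needs_cohort, collapse = ", "),
         " need a cohort: include 'simulate' or supply `cohort`")
  structure(list(n = n, seed = as.integer(seed), stages = stages,
                 models = models, out_dir = out_dir, pollutants = pollutants,
                 cohort = cohort, digits = digits),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path file path; format chosen by extension (.json / .yml / .yaml,
#'   YAML requires the `yaml` package).
#' @return a validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::fromJSON(path)
  else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else stop("unsupported config extension: ", ext)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order, writes one CSV per stage plus a
#' run manifest (JSON) to the configured output directory, and returns the
#' in-memory results. Deterministic: identical (config, seed) gives
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()] or a path readable by
#'   [read_pipeline_config()].
#' @return invisible named list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  warn_count <- 0
  wfile <- function(name, df) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    write.csv(df, path, row.names = FALSE)
    path
  }
  cohort <- config$cohort
  if ("simulate" %in% config$stages) {
    cohort <- simulate_cohort(n = config$n, seed = config$seed)
    res$cohort <- cohort
    wfile("cohort", cohort)
  }
  if ("score" %in% config$stages) {
    scored <- score_cohort(cohort, example_risk_table())
    scored$class <- as.character(classify_risk(pmin(pmax(scored$risk, 0), 1)))
    res$score <- scored
    wfile("risk_scores", scored)
  }
  conc_stages <- intersect(c("concentration", "proportion", "residual"),
                           config$stages)
  if (length(conc_stages)) {
    parts <- list()
    for (m in config$models) {
      if ("concentration" %in% conc_stages)
        parts[[paste0("c", m)]] <- run_concentration_analysis(
          cohort, model = m, pollutants = config$pollutants)
      if ("proportion" %in% conc_stages)
        parts[[paste0("p", m)]] <- run_proportion_analysis(cohort, model = m)
      if ("residual" %in% conc_stages)
        parts[[paste0("r", m)]] <- run_residual_analysis(cohort, model = m)
    }
    res$constituent_models <- do.call(rbind, parts)
    rownames(res$constituent_models) <- NULL
    wfile("constituent_models", res$constituent_models)
  }
  if ("ism" %in% config$stages) {
    res$ism <- substitution_matrix(cohort, model = max(config$models))
    wfile("ism_matrix", as.data.frame(res$ism))
  }
  if ("spline" %in% config$stages) {
    curves <- lapply(config$pollutants, function(p)
      fit_spline_curve(cohort, p, model = max(config$models)))
    names(curves) <- config$pollutants
    res$spline <- curves
    nl <- data.frame(pollutant = config$pollutants,
                     p_nonlinear = vapply(curves, function(cu)
                       cu$p_nonlinear, numeric(1)))
    wfile("spline_nonlinearity", nl)
    for (p in config$pollutants)
      wfile(paste0("spline_", p), curves[[p]]$curve)
  }
  if ("stratify" %in% config$stages) {
    res$stratified <- run_stratified_analysis(
      cohort, pollutants = config$pollutants, model = max(config$models))
    wfile("stratified", res$stratified)
  }
  if ("sensitivity" %in% config$stages) {
    series <- generate_monthly_series(cohort,
                                      pollutants = config$pollutants,
                                      seed = stage_seed(config$seed, 9))
    res$sensitivity <- sensitivity_by_window(
      cohort, series, pollutants = config$pollutants,
      model = max(config$models))
    wfile("sensitivity", res$sensitivity)
  }
  if ("report" %in% config$stages) {
    res$table1 <- summarize_table1(cohort)
    wfile("table1", res$table1)
    if (!is.null(res$constituent_models)) {
      cm <- res$constituent_models
      cm$estimate <- paste0(fmt_num(cm$or, config$digits), " (",
                            fmt_num(cm$ci_low, config$digits), ", ",
                            fmt_num(cm$ci_high, config$digits), ")")
      res$report <- cm[c("method", "pollutant", "model", "estimate")]
      wfile("report_constituents", res$report)
    }
  }
  manifest <- list(package = "pm25ascvd",
                   version = as.character(packageVersion("pm25ascvd")),
                   seed = config$seed, n = if (!is.null(cohort)) nrow(cohort)
                   else config$n,
                   stages = config$stages, models = config$models)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
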