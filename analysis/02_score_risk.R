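#!/usr/bin/env Rscript
# Stage 2 — 10-year risk scoring.
#
# Scores the cohort with the table-driven Cox-score engine using the shipped
# synthetic coefficient tables (the published China-PAR coefficients are
# supplied by the user in the same JSON schema), and classifies predicted
# risk at the 10% threshold.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

cohort <- build_cohort()
tabs <- example_risk_table()
scored <- score_cohort(cohort, tabs)
scored$class <- as.character(classify_risk(pmin(pmax(scored$risk, 0), 1)))

cat(sprintf("Scored %d participants with the synthetic example tables\n",
            nrow(scored)))
cat(sprintf("Median predicted 10-year risk: %.3f%%\n",
            100 * median(scored$risk)))
cat(sprintf("Classified high (>= 10%%): %d (%.3f%%)\n",
            sum(scored$high_risk),
            100 * mean(scored$high_risk)))

summ <- data.frame(
  statistic = c("n", "median_risk", "mean_risk", "n_high", "pct_high"),
  value = c(nrow(scored), median(scored$risk), mean(scored$risk),
            sum(scored$high_risk), 100 * mean(scored$high_risk)))
write.csv(summ, "results/risk_summary.csv", row.names = FALSE)
cat("Summary -> results/risk_summary.csv\n")
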