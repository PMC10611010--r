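# Shared setup for the analysis drivers: one master seed, one cohort.
# Every script can be run standalone; the cohort is rebuilt deterministically.

suppressPackageStartupMessages(library(pm25ascvd))

SEED <- 20231L
N_COHORT <- 31162L   # analysed cohort size after the exclusion cascade

dir.create("results", showWarnings = FALSE)

build_cohort <- function(n = N_COHORT, seed = SEED) {
  simulate_cohort(n = n, seed = seed)
}
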