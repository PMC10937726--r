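#!/usr/bin/env Rscript
# Phenotype incident PD cohorts from the simulated sources: first observed PD
# diagnosis, 730-day quiescence (encounter-based for the EMR, coverage-based
# for claims; research cohorts enter with an explicit diagnosis date),
# confirmatory diagnosis at >= 30 days, and parkinsonism-mimic exclusions.
# Writes cohort.csv and attrition.json per source.

suppressPackageStartupMessages({
  library(pdprogression)
  library(jsonlite)
})

for (arch in c("research", "research_survey", "rwd_emr", "rwd_claims")) {
  dir <- file.path("results/data", arch)
  ds <- read_dataset(dir, arch)
  coh <- build_cohort(ds)
  print(coh)
  write.csv(coh$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  write_json(as.list(coh$attrition), file.path(dir, "attrition.json"),
             auto_unbox = TRUE)
}
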