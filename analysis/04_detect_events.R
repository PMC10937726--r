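#!/usr/bin/env Rscript
# Detect clinical events per included patient: PD-therapeutic and levodopa
# initiation via the fill-sequence episode rule, H&Y >= 3 threshold crossing
# from recorded scores, the utilization-based cognitive-decline proxy, and
# adverse events (falls/fractures, depression) with quiescence-window
# eligibility. Writes events.csv per source.

suppressPackageStartupMessages(library(pdprogression))

for (arch in c("research", "rwd_emr", "rwd_claims")) {
  dir <- file.path("results/data", arch)
  ds <- read_dataset(dir, arch)
  coh <- build_cohort(ds)
  scores <- analysis_scores(ds)
  ev <- detect_events(ds, coh, scores = scores)
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  obs <- tapply(ev$observed, ev$event_type, function(x) sum(x, na.rm = TRUE))
  cat(arch, ": events observed:",
      paste(names(obs), obs, sep = "=", collapse = ", "), "\n")
}
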