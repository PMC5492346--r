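#!/usr/bin/env Rscript
# Classify the simulated cohort against the WBGT exposure-limit table and
# summarize it, checking that the generator's configured prevalences come
# back out. Reads results/synthetic/cohort.csv (run 01_simulate.R first).

suppressPackageStartupMessages(library(heatstrain))

out_dir <- "results/classification"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cases("results/synthetic/cohort.csv")
cls <- classify_cases(cohort, table = default_limit_table())
readr::write_csv(cls, file.path(out_dir, "classifications.csv"))

summary <- summarize_cohort(cohort, cls)
print(summary)
write_summary(summary,
              json_path = file.path(out_dir, "summary.json"),
              csv_path = file.path(out_dir, "summary.csv"))

cat(sprintf("\n%d of %d simulated workers (%.1f%%) reached their WBGT limit\n",
            summary$factors$count[summary$factors$measure == "exceeds_limit"],
            summary$n_total,
            summary$factors$pct[summary$factors$measure == "exceeds_limit"]))
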