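#!/usr/bin/env Rscript
# Clean the raw herd with the AMS processing rules: 3-SD outlier removal
# with the 30-day abnormal-behaviour exception, removal of cows culled
# before 50 DIM, the 5-305 DIM window, the 90% completeness filter, AFC
# quartile coding and the warm/cold season flag.
suppressPackageStartupMessages(library(herdsurv))

herd <- read_herd("results/herd")
pp <- preprocess_herd(herd)

rep <- pp$report
cat(sprintf("input cows: %d\n", rep$filters$input_cows))
cat(sprintf("  culled before 50 DIM: %d\n", rep$filters$culled_before_50))
cat(sprintf("  below 90%% completeness: %d\n", rep$filters$incomplete_cows))
cat(sprintf("  outlier cow-days removed: %d\n", rep$outlier_rows_removed))
cat(sprintf("retained cows: %d\n", rep$filters$retained_cows))

dir.create("results/clean", showWarnings = FALSE, recursive = TRUE)
write.csv(pp$herd$sensor, "results/clean/sensor.csv", row.names = FALSE)
write.csv(pp$herd$cows, "results/clean/cows.csv", row.names = FALSE)
write.csv(pp$herd$survival, "results/clean/survival.csv", row.names = FALSE)
jsonlite::write_json(
  list(outlier_rows_removed = rep$outlier_rows_removed,
       filters = rep$filters[c("input_cows", "culled_before_50",
                               "rows_outside_5_305", "incomplete_cows",
                               "retained_cows")]),
  "results/clean/cleaning_report.json", auto_unbox = TRUE, digits = NA)
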