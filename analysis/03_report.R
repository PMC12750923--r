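#!/usr/bin/env Rscript
# Step 3: tabulate and plot the cohort results.
#
# Reads results/cohort_run/ (from analysis/02_run_cohort.R) and writes
# results/report/: a pooled-summary CSV and a figure of per-pair median CP
# distances by group and bone.
#
# Usage: Rscript analysis/03_report.R

suppressPackageStartupMessages(library(osteosym))

run_dir <- file.path("results", "cohort_run")
per_pair_csv <- file.path(run_dir, "per_pair_summaries.csv")
report_json <- file.path(run_dir, "cohort_report.json")
if (!file.exists(per_pair_csv)) {
  stop("no cohort results at ", run_dir, "; run analysis/02_run_cohort.R first")
}
out_dir <- file.path("results", "report")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

per_pair <- read.csv(per_pair_csv)
report <- jsonlite::read_json(report_json, simplifyVector = TRUE)
pooled <- report$pooled

write.csv(pooled, file.path(out_dir, "pooled_summaries.csv"),
          row.names = FALSE)
message("pooled group summaries (mm):")
print(pooled, row.names = FALSE)

# per-pair medians by group, one panel per bone
groups <- c("none", "low", "high")
bones <- sort(unique(per_pair$bone))
png(file.path(out_dir, "medians_by_group.png"),
    width = 320 * length(bones), height = 360)
par(mfrow = c(1, length(bones)), mar = c(4, 4, 3, 1))
for (b in bones) {
  d <- per_pair[per_pair$bone == b, ]
  d$group <- factor(d$group, levels = groups)
  stripchart(median ~ group, data = d, vertical = TRUE, pch = 19,
             method = "jitter", jitter = 0.08, col = "#2c6e9e",
             ylim = c(0, max(per_pair$median) * 1.1),
             ylab = "median CP distance (mm)", main = b)
  meds <- tapply(d$median, d$group, median)
  segments(seq_along(meds) - 0.2, meds, seq_along(meds) + 0.2, meds,
           lwd = 2, col = "#b03030")
}
dev.off()
message("wrote ", file.path(out_dir, "medians_by_group.png"))
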