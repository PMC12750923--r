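#!/usr/bin/env Rscript
# Step 2: run the symmetry pipeline over the simulated cohort.
#
# Reads results/cohort/manifest.csv (from analysis/01_simulate.R), processes
# every pair (mirror -> rigid CPD -> trim-and-register -> nonrigid CPD ->
# CP distances), and writes per-pair summaries, the JSON cohort report,
# PLY/PNG heatmaps and a run log to results/cohort_run/.
#
# Usage: Rscript analysis/02_run_cohort.R [config.yaml] [seed]

suppressPackageStartupMessages(library(osteosym))

args <- commandArgs(trailingOnly = TRUE)
config <- if (length(args) >= 1) read_config(args[1]) else default_config()
if (length(args) >= 2) config$seed <- as.integer(args[2])

manifest <- file.path("results", "cohort", "manifest.csv")
if (!file.exists(manifest)) {
  stop("no cohort manifest at ", manifest,
       "; run analysis/01_simulate.R first")
}
out_dir <- file.path("results", "cohort_run")
report <- run_cohort(manifest, config, out_dir = out_dir, heatmaps = TRUE)
print(report)
if (nrow(report$failures)) {
  message("failed pairs:")
  print(report$failures, row.names = FALSE)
}
message("outputs in ", out_dir)
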