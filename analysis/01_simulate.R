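#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# Writes left/right STL surface models plus a manifest to results/cohort/.
# Three groups of increasing injected asymmetry (none / low / high), two
# subjects per group, femur + patella + tibia per subject.
#
# Usage: Rscript analysis/01_simulate.R [n_per_group] [seed]

suppressPackageStartupMessages(library(osteosym))

args <- commandArgs(trailingOnly = TRUE)
n_per_group <- if (length(args) >= 1) as.integer(args[1]) else 2L
seed <- if (length(args) >= 2) as.integer(args[2]) else 11L

out_dir <- file.path("results", "cohort")
manifest <- write_fixture_cohort(out_dir, n_per_group = n_per_group,
                                 seed = seed)
tab <- read.csv(manifest)
message(sprintf("wrote %d pairs (%d subjects x %d bones) to %s",
                nrow(tab), length(unique(tab$subject_id)),
                length(unique(tab$bone)), out_dir))
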