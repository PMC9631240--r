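#!/usr/bin/env Rscript

# Stage 1: simulate the study inputs.
#
# Builds a synthetic genome with known ground truth -- planted MiDAS-like
# enrichment sites in early-replicating, highly transcribed, R-loop-marked
# genes -- together with a mitotic nascent-DNA count track and a two-cohort
# tumor rearrangement catalog, and writes everything as pipeline-ready flat
# files under data/world/.
#
# Usage: Rscript analysis/01_simulate_world.R [--seed <int>]

suppressPackageStartupMessages(library(midasmap))

args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) as.integer(args[match("--seed", args) + 1]) else 1L

cfg <- synthetic_config() # 2 x 50 Mb at 10-kb bins, 20 sites at 8-fold
truth <- generate_world(cfg, seed = seed)
counts <- simulate_bin_counts(truth, seed = seed + 1000L)
svs <- simulate_sv_catalog(truth, seed = seed + 2000L)

dir <- "data/world"
write_world(truth, dir, counts = counts, svs = svs)

cat(sprintf(
  "world seed %d: %d genes, %d origins, %d R-loop peaks, %d planted sites -> %s\n",
  seed, nrow(truth$genes), nrow(truth$origins), nrow(truth$rloops),
  nrow(truth$sites), dir
))
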