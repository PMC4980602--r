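#!/usr/bin/env Rscript
# Simulate the reference crystal and write the unmerged/merged reflection
# files plus the stage log under results/pipeline/.
# Usage: Rscript analysis/02_simulate.R [--seed <int>]

suppressPackageStartupMessages(library(nsad))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

cfg <- pipeline_config(seed = seed, out_dir = "results/pipeline")
report <- run_pipeline(cfg, verbose = TRUE)
cat(sprintf("wrote results/pipeline (seed %d)\n", seed))
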