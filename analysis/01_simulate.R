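#!/usr/bin/env Rscript
# Step 1: simulate the study's recordings and write them as portable
# fixtures (16-bit TIFF + ground truth + protocol). Later steps read only
# these fixtures, never the in-memory simulation, so the whole analysis
# can be re-run from disk.

suppressPackageStartupMessages(library(dcvtrace))

out_root <- file.path("results", "fixtures")
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

# pHluorin-cargo cells: 2 Hz / 90 s, 16 x 50 AP @ 50 Hz at t = 30 s,
# NH4+ de-quench during the last 10 s to reveal the total pool
protocol <- build_protocol(nh4_start_s = 80, nh4_duration_s = 10)
for (seed in 1:6) {
  sim <- simulate_scene(scene_config(rng_seed = seed), protocol)
  dir <- file.path(out_root, sprintf("cell%02d_phluorin", seed))
  write_fixture(sim, dir)
  cat("wrote", dir, ":", nrow(sim$truth$events), "true fusion events\n")
}

# red-cargo cells (pH-insensitive): used for full-release detection and
# for tracking cargo that is visible before fusion
for (seed in 101:103) {
  sim <- simulate_scene(scene_config(rng_seed = seed, reporter = "red"),
                        build_protocol())
  dir <- file.path(out_root, sprintf("cell%02d_red", seed - 100))
  write_fixture(sim, dir)
  cat("wrote", dir, ":", nrow(sim$truth$events), "true full-release events\n")
}

cat("done\n")
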