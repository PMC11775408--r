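#!/usr/bin/env Rscript
# Simulate the paired study cohort: 28 synthetic glioma-like lesions, each
# observed once at high resolution (0.75 mm isotropic) and once on a
# clinical-style anisotropic grid (0.4 x 0.4 x 5 mm), written as NIfTI masks
# plus a manifest. All downstream steps read only these files.

library(glioshape)

master_seed <- 1L
out_dir <- "results/cohort"

message("Simulating 28 paired lesion masks (this takes a few minutes) ...")
manifest <- make_paired_cohort(28L, scenario_default(), master_seed = master_seed,
                               dir = out_dir)
man <- read_manifest(as.character(manifest))
message(sprintf("Wrote %d subjects (%d mask files) under %s",
                nrow(man), 2 * nrow(man), out_dir))
message("Scenario parameters are recorded in ", file.path(out_dir, "scenario.txt"))
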