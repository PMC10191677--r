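#!/usr/bin/env Rscript
# Simulate the raw materials of a contractility screen: one rendered well at
# the full acquisition scale (2x2 fields of 1137 px at 10% overlap -> a
# 2160x2160 stitched mosaic at 1.35 um/px), written as per-channel TIFF
# stacks with a ground-truth sidecar, plus the truth table of a whole
# replicated 96-well kinase screen.

suppressMessages(library(micropost))
dir.create("results/wells", recursive = TRUE, showWarnings = FALSE)

## One full-scale well: unseeded baseline geometry with a tissue at 40%
## contraction of the 1800 um baseline spacing.
spec <- scene_spec(true_tip_distance = 1800 * 0.6, seed = 101L)
scene <- generate_scene(spec)
paths <- write_well_images(scene, "results/wells", "C4")
cat("rendered well C4:",
    sprintf("true tip distance %.0f um, tissue area %.4f mm^2\n",
            scene$truth$tip_distance_true_um,
            scene$truth$tissue_area_true_mm2))
cat("wrote:", paste(basename(paths), collapse = ", "), "\n")

## Whole-plate screen truth: 18 TGF-beta1 control wells and 13 compounds
## (5 active) in 2 biological x 3 technical replicates, with two damaged
## wells and a staurosporine-style dead control in B6.
design <- kinase_screen_design(damaged_wells = c("D7", "F2"),
                               dead_wells = "B6", seed = 202L)
sim <- simulate_screen(design)
write_plate_csv(sim, "results/plate_truth.csv")
cat(sprintf("simulated plate: %d wells, %d conditions, %d damaged, %d dead\n",
            nrow(sim$table), length(unique(sim$table$condition)),
            sum(sim$table$damaged), sum(sim$table$dead)))
cat("wrote: results/plate_truth.csv\n")
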