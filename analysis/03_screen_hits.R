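#!/usr/bin/env Rscript
# Plate-level hit calling on the simulated kinase screen: exclude damaged and
# dead wells, average technical into biological replicates, and call hits at
# 3x the raw median absolute deviation below the treated-control median.

suppressMessages(library(micropost))
dir.create("results", showWarnings = FALSE)

design <- kinase_screen_design(damaged_wells = c("D7", "F2"),
                               dead_wells = "B6", seed = 202L)
sim <- simulate_screen(design)

agg <- aggregate_and_exclude(sim$table)
excluded <- agg$wells[agg$wells$excluded, c("well_id", "exclusion_reason")]
cat(sprintf("excluded %d of %d wells: %s\n", nrow(excluded),
            nrow(agg$wells),
            paste(sprintf("%s (%s)", excluded$well_id,
                          excluded$exclusion_reason), collapse = ", ")))

report <- call_hits(agg, "TGFB1", k_mad = 3)
print(report)
write_hit_report(report, "results/hit_report")
utils::write.csv(agg$wells, "results/screen_wells.csv", row.names = FALSE)

injected <- sprintf("inhibitor%02d", 1:5)
cat(sprintf("injected actives recovered: %d/5; false positives: %d\n",
            sum(injected %in% report$hits),
            sum(!report$hits %in% injected)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  ggplot2::ggsave("results/plate_heatmap.png", plot_plate(agg$wells),
                  width = 8, height = 5, dpi = 150)
  cat("wrote: results/plate_heatmap.png\n")
}
cat("wrote: results/hit_report.csv, results/hit_report.json,",
    "results/screen_wells.csv\n")
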