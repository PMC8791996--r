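#!/usr/bin/env Rscript
# Generate the synthetic study dataset: per-section ODR observations from a
# ten-area, five-level ground truth (80 of 90 directed pathways observed),
# a set of rendered laminar section images, and receptive-field response
# maps whose mean diameters increase with hierarchical level.

library(hierODR)

seed <- 20260101L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config()
sim <- simulate_odr(cfg, seed = seed)
write_edge_table(sim$observations, file.path(out, "edge_table.tsv"))
write_area_catalog(cfg$catalog, file.path(out, "areas.json"))
jsonlite::write_json(
  list(levels = as.list(sim$truth$levels), phi = sim$truth$phi,
       missing = sim$truth$missing, seed = seed),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

# a few rendered sections spanning the feedback-to-feedforward ODR range
dir.create(file.path(out, "images"), showWarnings = FALSE)
for (target in c(0.2, 0.35, 0.5, 0.65, 0.8)) {
  r <- render_laminar_image(target, noise_sd = 3, seed = seed + round(100 * target))
  stem <- file.path(out, "images", sprintf("section_odr%02.0f", 100 * target))
  write_laminar_image(r$image, paste0(stem, ".png"), paste0(stem, ".json"))
}

rf <- simulate_rf_maps(setNames(8 + 12 * sim$truth$levels,
                                names(sim$truth$levels)),
                       units_per_area = 8, noise_sd = 1, seed = seed)
write.table(rf$maps, file.path(out, "rf_maps.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rf$truth, file.path(out, "rf_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Simulated ", nrow(unique(sim$observations[c("source", "target")])),
        " pathways (", nrow(sim$truth$missing), " missing), ",
        length(unique(rf$maps$unit_id)), " RF units; written to ", out)
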