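#!/usr/bin/env Rscript
# Stage 1: simulate the field trial.
#
# Generates the 48-plot randomized block layout (2 varieties x 8 treatments
# x 3 replicates), disc-weighing ground-truth LAI for the three growth
# stages, and one 125-band hyperspectral cube per stage. Artifacts are
# written under results/run/ so every later stage can restart from disk.

suppressPackageStartupMessages(library(canopylai))

out <- "results/run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- default_config(seed = 0)
write_run_config(cfg, file.path(out, "config.json"))

layout <- make_layout(cfg$seed, pixel_size = cfg$pixel_size)
write_layout_geojson(layout, file.path(out, "layout.geojson"))
truth <- simulate_lai_all_stages(layout, seed = cfg$seed,
                                 noise_sd = cfg$lai_noise_sd)
write.csv(truth, file.path(out, "ground_truth.csv"), row.names = FALSE)

cat(sprintf("%d plots x %d stages = %d LAI samples\n",
            nrow(layout), length(cfg$stages), nrow(truth)))
for (st in cfg$stages) {
  lai <- truth$lai[truth$stage == st]
  cat(sprintf("  %s: LAI %.2f-%.2f, mean %.2f\n", st, min(lai), max(lai),
              mean(lai)))
  cube <- simulate_cube(layout, truth, st, seed = cfg$seed,
                        k_ext = cfg$k_ext,
                        k_ext_jitter_sd = cfg$k_ext_jitter_sd,
                        noise_sd = cfg$noise_sd,
                        roughness_base = cfg$roughness_base,
                        rough_jitter_sd = cfg$rough_jitter_sd,
                        stripe_amp = cfg$stripe_amp, illum_sd = cfg$illum_sd,
                        illum_scale_px = cfg$illum_scale_px,
                        micro_amp = cfg$micro_amp,
                        soil_moist_sd = cfg$soil_moist_sd,
                        soil_moist_scale_px = cfg$soil_moist_scale_px)
  write_cube_envi(cube, file.path(out, paste0("cube_", st)))
  cat(sprintf("    cube %d x %d x %d written\n", dim(cube$values)[1],
              dim(cube$values)[2], dim(cube$values)[3]))
}
cat("done: layout.geojson, ground_truth.csv, cube_*.bsq/.hdr under", out, "\n")
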