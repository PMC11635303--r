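#!/usr/bin/env Rscript
# Stage 5: per-pixel LAI maps.
#
# Applies the best validation model pixel-wise to every stage cube (spectral
# features from the pixel spectrum, texture features from the window centered
# on the pixel) and writes one masked LAI raster per growth stage.

suppressPackageStartupMessages(library(canopylai))

out <- "results/run"
cfg <- read_run_config(file.path(out, "config.json"))
features <- read_feature_table(file.path(out, "features.csv"))
truth <- read.csv(file.path(out, "ground_truth.csv"))
layout <- make_layout(cfg$seed, pixel_size = cfg$pixel_size)
idx <- match(paste(features$plot_id, features$stage),
             paste(truth$plot_id, truth$stage))
samples <- truth[idx, ]
reports <- read.csv(file.path(out, "model_reports.csv"))
val <- reports[reports$split == "validation", ]
best <- val[which.max(val$r2), ]
cat(sprintf("mapping with %s + %s (validation R2 %.2f)\n",
            best$family, best$method, best$r2))

split <- make_split(samples)
fam_tags <- feature_families(features)
cols_all <- setdiff(colnames(features), c("plot_id", "stage"))
cols <- if (best$family == "ALL") cols_all else
  names(fam_tags)[fam_tags == best$family]
sel <- spa_select(features[split$calibration, cols, drop = FALSE],
                  samples$lai[split$calibration], kmax = cfg$spa_kmax,
                  folds = cfg$spa_folds,
                  seed = derive_seed(cfg$seed, 101L,
                                     match(best$family, cfg$families)))
fit <- fit_lai_model(best$method,
                     as.matrix(features[split$calibration,
                                        sel$chosen_columns, drop = FALSE]),
                     samples$lai[split$calibration],
                     seed = derive_seed(cfg$seed, 103L,
                                        match(best$family, cfg$families),
                                        match(best$method, cfg$methods)))

for (st in cfg$stages) {
  cube <- read_cube_envi(file.path(out, paste0("cube_", st)))
  cube$stage <- st
  map <- write_lai_map(fit, sel$chosen_columns, cube, layout, config = cfg,
                       clip_range = c(0, 5))
  map_cube <- reflectance_cube(array(ifelse(is.na(map), -9999, map),
                                     dim = c(dim(map), 1L)),
                               wavelengths = 0, pixel_size = cfg$pixel_size)
  write_cube_envi(map_cube, file.path(out, paste0("lai_map_", st)))
  cat(sprintf("  %s: predicted LAI %.2f-%.2f over %d plot pixels\n", st,
              min(map, na.rm = TRUE), max(map, na.rm = TRUE),
              sum(!is.na(map))))
}
cat("LAI maps written under", out, "\n")
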