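#!/usr/bin/env Rscript
# Stage 4: fit and evaluate the regression grid.
#
# PLSR, random forest and Gaussian process regressions on the SPA-selected
# subsets of each feature family and of the combined table, trained on
# replicates 2-3 (96 samples) and validated on replicate 1 (48 samples),
# with a per-stage breakdown of the best validation model.

suppressPackageStartupMessages(library(canopylai))

out <- "results/run"
cfg <- read_run_config(file.path(out, "config.json"))
features <- read_feature_table(file.path(out, "features.csv"))
truth <- read.csv(file.path(out, "ground_truth.csv"))
idx <- match(paste(features$plot_id, features$stage),
             paste(truth$plot_id, truth$stage))
samples <- truth[idx, ]

res <- run_experiment(features, samples, methods = cfg$methods,
                      families = cfg$families, spa_kmax = cfg$spa_kmax,
                      spa_folds = cfg$spa_folds, seed = cfg$seed)
write.csv(res$reports, file.path(out, "model_reports.csv"), row.names = FALSE)
write.csv(res$per_stage, file.path(out, "per_stage_validation.csv"),
          row.names = FALSE)
print(res)
cat("\nper-stage validation of the best model:\n")
print(res$per_stage, row.names = FALSE)

# measured-vs-estimated scatter data for the best model
best_fit <- res$models[[res$best$family]][[res$best$method]]
cols <- res$selected[[res$best$family]]$chosen_columns
pred <- predict(best_fit, as.matrix(features[, cols, drop = FALSE]))
scatter <- data.frame(plot_id = samples$plot_id, stage = samples$stage,
                      split = ifelse(seq_len(nrow(samples)) %in%
                                       res$split$validation,
                                     "validation", "calibration"),
                      measured = samples$lai, estimated = pred)
write.csv(scatter, file.path(out, "measured_vs_estimated.csv"),
          row.names = FALSE)
cat(sprintf("\nscatter data for %s + %s written\n",
            res$best$family, res$best$method))
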