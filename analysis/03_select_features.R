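#!/usr/bin/env Rscript
# Stage 3: successive-projections feature selection.
#
# Runs SPA (exhaustive starts, SPA-MLR with repeated 5-fold RMSECV) on the
# calibration replicates for every feature family and for the combined
# 308-column table, writing the chosen subsets as JSON and a summary table.

suppressPackageStartupMessages(library(canopylai))

out <- "results/run"
cfg <- read_run_config(file.path(out, "config.json"))
features <- read_feature_table(file.path(out, "features.csv"))
truth <- read.csv(file.path(out, "ground_truth.csv"))
idx <- match(paste(features$plot_id, features$stage),
             paste(truth$plot_id, truth$stage))
samples <- truth[idx, ]
split <- make_split(samples)
fam_tags <- feature_families(features)
feat_cols <- setdiff(colnames(features), c("plot_id", "stage"))

rows <- list()
for (fam in c("OSR", "FDSR", "VI", "TEX", "ALL")) {
  cols <- if (fam == "ALL") feat_cols else names(fam_tags)[fam_tags == fam]
  sel <- spa_select(features[split$calibration, cols, drop = FALSE],
                    samples$lai[split$calibration],
                    kmax = cfg$spa_kmax, folds = cfg$spa_folds,
                    seed = cfg$seed)
  write_spa_result(sel, file.path(out, paste0("spa_", fam, ".json")))
  cat(sprintf("%-4s %3d candidates -> %2d selected (RMSECV %.3f): %s\n",
              fam, length(cols), sel$chosen_k, sel$rmsecv,
              paste(sel$chosen_columns, collapse = ", ")))
  rows[[fam]] <- data.frame(family = fam, n_candidates = length(cols),
                            n_selected = sel$chosen_k, rmsecv = sel$rmsecv,
                            features = paste(sel$chosen_columns,
                                             collapse = "; "))
}
write.csv(do.call(rbind, rows), file.path(out, "selected_features.csv"),
          row.names = FALSE)
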