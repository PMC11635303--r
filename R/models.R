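#' Replicate-based calibration/validation split
#'
#' Deterministic partition of the sample table: replicates 2 and 3 of every
#' growth stage form the calibration (training) set, replicate 1 the
#' validation set — 96 / 48 samples on the full three-stage design.
#'
#' @param samples data.frame with a `replicate` column (e.g. ground truth).
#' @return a `split_plan`: list with integer row indices `calibration` and
#'   `validation`.
#' @export
make_split <- function(samples) {
  if (!"replicate" %in% colnames(samples)) {
    stop("samples must carry a `replicate` column", call. = FALSE)
  }
  cal <- which(samples$replicate %in% c(2L, 3L))
  val <- which(samples$replicate == 1L)
  if (!length(cal)) stop("empty calibration set: only replicate 1 present", call. = FALSE)
  structure(list(calibration = cal, validation = val), class = "split_plan")
}

#' Fit one LAI regression model
#'
#' Dispatcher over the three regression methods. Hyperparameter defaults:
#' PLSR components by internal 5-fold CV up to 10; RFR with `ntree = 500`,
#' `mtry = max(1, floor(p/3))`; GPR with a squared-exponential kernel tuned
#' by marginal likelihood.
#'
#' @param method one of "PLSR", "RFR", "GPR".
#' @param X predictor matrix or data.frame (feature columns only).
#' @param y response vector.
#' @param seed integer seed (CV folds / bootstrap).
#' @param ... passed to the method-specific fitter.
#' @return the fitted model (`plsr_fit`, `rfr_fit` or `gpr_fit`).
#' @export
fit_lai_model <- function(method = c("PLSR", "RFR", "GPR"), X, y, seed = 0L, ...) {
  method <- match.arg(method)
  X <- as.matrix(X)
  switch(method,
         PLSR = fit_plsr(X, y, seed = seed, ...),
         RFR = fit_rfr(X, y, seed = seed, ...),
         GPR = fit_gpr(X, y, seed = seed, ...))
}

#' Accuracy metrics for predicted vs measured LAI
#'
#' Standard forms: `R2 = 1 - SSE/SST`, `RMSE = sqrt(mean((y - yhat)^2))`,
#' `NRMSE = 100 * RMSE / mean(y)` (percent of the measured mean).
#'
#' @param measured measured values.
#' @param predicted predicted values.
#' @return an `eval_report`: list with `r2`, `rmse`, `nrmse_percent`, `n`,
#'   and a `predictions` data.frame.
#' @export
evaluate_predictions <- function(measured, predicted) {
  n <- length(measured)
  if (n == 0 || n != length(predicted)) stop("non-empty, equal-length vectors required",
                                             call. = FALSE)
  sst <- sum((measured - mean(measured))^2)
  if (sst < 1e-300) stop("zero-variance measured vector: R2 undefined", call. = FALSE)
  sse <- sum((measured - predicted)^2)
  rmse <- sqrt(mean((measured - predicted)^2))
  structure(list(r2 = 1 - sse / sst, rmse = rmse,
                 nrmse_percent = 100 * rmse / mean(measured), n = n,
                 predictions = data.frame(measured = measured,
                                          predicted = predicted)),
            class = "eval_report")
}

#' Full model-comparison experiment
#'
#' For each feature family (OSR, FDSR, VI, TEX) and the combined table (ALL):
#' select features by SPA on the calibration rows, fit the three regression
#' methods on the calibration rows, and evaluate on both splits — a
#' 5 x 3 x 2 report grid — plus a per-stage validation breakdown for the best
#' validation model.
#'
#' @param features the combined `feature_table` (keys + 308 feature columns).
#' @param samples sample table aligned with `features` rows, carrying
#'   `replicate`, `stage` and `lai`.
#' @param methods regression methods (default all three).
#' @param families feature families (default OSR, FDSR, VI, TEX, ALL).
#' @param spa_kmax,spa_folds SPA controls (see [spa_select()]).
#' @param spa_on rows used for feature selection: `"calibration"` (default;
#'   strictly leakage-free with respect to the validation replicate) or
#'   `"all"` (selection precedes modeling on the full sample set, as
#'   published protocols in this field typically do).
#' @param seed integer master seed.
#' @return an `experiment_result`: list with `reports` (long data.frame),
#'   `per_stage`, `selected` (named list of SPA results), `models` (nested
#'   list), `split`, `best` (family/method of best validation R2).
#' @export
run_experiment <- function(features, samples,
                           methods = c("PLSR", "RFR", "GPR"),
                           families = c("OSR", "FDSR", "VI", "TEX", "ALL"),
                           spa_kmax = NULL, spa_folds = 5L,
                           spa_on = c("calibration", "all"), seed = 0L) {
  spa_on <- match.arg(spa_on)
  stopifnot(nrow(features) == nrow(samples))
  fam_tags <- feature_families(features)
  feat_cols <- setdiff(colnames(features), c("plot_id", "stage"))
  split <- make_split(samples)
  y <- samples$lai
  reports <- list()
  selected <- list()
  models <- list()
  for (fam in families) {
    cols <- if (fam == "ALL") feat_cols else names(fam_tags)[fam_tags == fam]
    Xfam <- features[, cols, drop = FALSE]
    sel_rows <- if (spa_on == "all") seq_len(nrow(features)) else split$calibration
    spa <- spa_select(Xfam[sel_rows, , drop = FALSE], y[sel_rows],
                      kmax = spa_kmax, folds = spa_folds,
                      seed = derive_seed(seed, 101L, match(fam, families)))
    selected[[fam]] <- spa
    Xsel <- as.matrix(Xfam[, spa$chosen_columns, drop = FALSE])
    models[[fam]] <- list()
    for (m in methods) {
      fit <- fit_lai_model(m, Xsel[split$calibration, , drop = FALSE],
                           y[split$calibration],
                           seed = derive_seed(seed, 103L, match(fam, families),
                                              match(m, methods)))
      models[[fam]][[m]] <- fit
      for (sp in c("calibration", "validation")) {
        idx <- split[[sp]]
        ev <- evaluate_predictions(y[idx], predict(fit, Xsel[idx, , drop = FALSE]))
        reports[[length(reports) + 1L]] <-
          data.frame(family = fam, method = m, split = sp,
                     r2 = ev$r2, rmse = ev$rmse,
                     nrmse_percent = ev$nrmse_percent, n = ev$n,
                     n_features = ncol(Xsel), stringsAsFactors = FALSE)
      }
    }
  }
  reports <- do.call(rbind, reports)
  val <- reports[reports$split == "validation", ]
  best_row <- val[which.max(val$r2), ]
  best_fit <- models[[best_row$family]][[best_row$method]]
  best_cols <- selected[[best_row$family]]$chosen_columns
  per_stage <- lapply(unique(samples$stage), function(st) {
    idx <- intersect(split$validation, which(samples$stage == st))
    Xsel <- as.matrix(features[, best_cols, drop = FALSE])
    ev <- evaluate_predictions(y[idx], predict(best_fit, Xsel[idx, , drop = FALSE]))
    data.frame(stage = st, family = best_row$family, method = best_row$method,
               r2 = ev$r2, rmse = ev$rmse, nrmse_percent = ev$nrmse_percent,
               n = ev$n, stringsAsFactors = FALSE)
  })
  structure(list(reports = reports, per_stage = do.call(rbind, per_stage),
                 selected = selected, models = models, split = split,
                 best = list(family = best_row$family, method = best_row$method)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("LAI estimation experiment\n")
  val <- x$reports[x$reports$split == "validation", ]
  for (i in seq_len(nrow(val))) {
    cat(sprintf("  %-4s %-4s validation R2 %.3f RMSE %.3f NRMSE %.1f%% (k=%d)\n",
                val$family[i], val$method[i], val$r2[i], val$rmse[i],
                val$nrmse_percent[i], val$n_features[i]))
  }
  cat(sprintf("best: %s + %s\n", x$best$family, x$best$method))
  invisible(x)
}
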