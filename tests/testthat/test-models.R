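test_that("replicate-based split yields the 96/48 partition", {
  lay <- make_layout(0)
  truth <- simulate_lai_all_stages(lay, seed = 0)
  sp <- make_split(truth)
  expect_length(sp$calibration, 96L)
  expect_length(sp$validation, 48L)
  expect_length(intersect(sp$calibration, sp$validation), 0L)
  expect_setequal(c(sp$calibration, sp$validation), seq_len(144))
  expect_true(all(truth$replicate[sp$validation] == 1L))
  # deterministic
  expect_identical(sp, make_split(truth))
  # degenerate single-replicate input
  expect_error(make_split(truth[truth$replicate == 1L, ]), "empty calibration")
  expect_error(make_split(data.frame(lai = 1:3)), "replicate")
})

test_that("evaluation metrics match their standard definitions", {
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ev$r2, ev$rmse, ev$nrmse_percent), c(1, 0, 0))
  ev2 <- evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
  expect_equal(ev2$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(ev2$nrmse_percent, 100 * sqrt(1 / 3) / 2, tolerance = 1e-12)
  expect_equal(round(ev2$nrmse_percent, 2), 28.87)
  # the null model scores exactly zero
  y <- c(0.4, 1.1, 2.7, 3.2)
  ev3 <- evaluate_predictions(y, rep(mean(y), 4))
  expect_equal(ev3$r2, 0, tolerance = 1e-12)
  expect_error(evaluate_predictions(rep(1, 3), rep(1, 3)), "zero-variance")
  expect_error(evaluate_predictions(numeric(0), numeric(0)), "non-empty")
  # oracle equivalence on random vectors
  set.seed(14)
  for (rep_i in 1:30) {
    ym <- rnorm(20); yp <- ym + rnorm(20, 0, 0.3)
    got <- evaluate_predictions(ym, yp)
    want <- oracle_metrics(ym, yp)
    expect_equal(got$r2, want$r2, tolerance = 1e-9)
    expect_equal(got$rmse, want$rmse, tolerance = 1e-9)
    expect_equal(got$nrmse_percent, want$nrmse, tolerance = 1e-9)
  }
})

test_that("PLSR recovers exact linear structure", {
  set.seed(15)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- X %*% c(1, -2, 0.5, 0, 3) + 4
  fit <- fit_plsr(X, y)
  ev <- evaluate_predictions(as.vector(y), predict(fit, X))
  expect_gte(ev$r2, 0.999)
  # coefficient path has one column per component, predictions vectorized
  expect_equal(length(predict(fit, X[1:3, , drop = FALSE])), 3L)
})

test_that("random forest regression is seeded and fits structure", {
  set.seed(16)
  X <- matrix(runif(80 * 4), 80, 4)
  y <- 2 * X[, 1] + sin(3 * X[, 2]) + rnorm(80, 0, 0.05)
  f1 <- fit_rfr(X, y, ntree = 100, seed = 5)
  f2 <- fit_rfr(X, y, ntree = 100, seed = 5)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_gte(evaluate_predictions(y, predict(f1, X))$r2, 0.8)
  # default hyperparameters follow the published rule
  expect_equal(fit_rfr(X, y, ntree = 10, seed = 1)$mtry, max(1L, floor(4 / 3)))
})

test_that("GPR recovers a smooth nonlinear function", {
  set.seed(17)
  x <- matrix(runif(60, -3, 3))
  y <- sin(x) + rnorm(60, 0, 0.05)
  fit <- fit_gpr(x[1:40, , drop = FALSE], y[1:40])
  ev <- evaluate_predictions(y[41:60], predict(fit, x[41:60, , drop = FALSE]))
  expect_gte(ev$r2, 0.9)
})

test_that("the model grid runs over 5 families x 3 methods x 2 splits", {
  # small synthetic table with a noiseless linear target
  set.seed(18)
  n <- 144
  stage <- rep(c("BBCH41", "BBCH44", "BBCH47"), each = 48)
  replicate <- rep(rep(1:3, each = 16), times = 3)
  mk <- function(p, prefix) {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0(prefix, seq_len(p))))
    m
  }
  X <- cbind(mk(4, "OSR_"), mk(4, "FDSR_"), mk(3, "VI_"), mk(3, "TEX_"))
  y <- as.vector(X[, 1] - 0.5 * X[, 5] + 0.8 * X[, 9] + 0.3 * X[, 12])
  tab <- data.frame(plot_id = rep(1:48, 3), stage = stage, X,
                    check.names = FALSE)
  attr(tab, "family") <- setNames(rep(c("OSR", "FDSR", "VI", "TEX"),
                                      c(4, 4, 3, 3)), colnames(X))
  class(tab) <- c("feature_table", "data.frame")
  samples <- data.frame(plot_id = tab$plot_id, stage = stage,
                        replicate = replicate, lai = y)
  res <- run_experiment(tab, samples, seed = 1)
  expect_equal(nrow(res$reports), 30L)
  expect_equal(sort(unique(res$reports$family)),
               sort(c("OSR", "FDSR", "VI", "TEX", "ALL")))
  expect_equal(sort(unique(res$reports$split)), c("calibration", "validation"))
  # the combined set carries the full signal: the linear and kernel methods
  # fit calibration essentially exactly; bootstrap-averaged trees sit a
  # little lower in-sample on a purely linear target
  cal_all <- res$reports[res$reports$family == "ALL" &
                           res$reports$split == "calibration", ]
  expect_true(all(cal_all$r2[cal_all$method != "RFR"] >= 0.95))
  expect_true(all(cal_all$r2[cal_all$method == "RFR"] >= 0.90))
  expect_equal(nrow(res$per_stage), 3L)
})
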