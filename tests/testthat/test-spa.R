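test_that("correlation screen reproduces the textbook Pearson formula", {
  set.seed(1)
  lai <- runif(20, 0.3, 3.5)
  X <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  X[, 1] <- lai                       # self-correlation
  X[, 2] <- -lai + 2                  # affine anticorrelation
  X[, 5] <- 1                         # zero variance
  sc <- correlation_screen(as.data.frame(X), lai)
  expect_equal(sc$r[1], 1, tolerance = 1e-12)
  expect_equal(sc$r[2], -1, tolerance = 1e-12)
  expect_true(sc$zero_variance[5] && is.na(sc$r[5]))
  # textbook formula oracle
  for (j in 3:4) {
    x <- X[, j]
    r_manual <- sum((x - mean(x)) * (lai - mean(lai))) /
      sqrt(sum((x - mean(x))^2) * sum((lai - mean(lai))^2))
    expect_equal(sc$r[j], r_manual, tolerance = 1e-12)
    t_manual <- r_manual * sqrt(18 / (1 - r_manual^2))
    expect_equal(sc$p[j], 2 * pt(-abs(t_manual), 18), tolerance = 1e-12)
  }
  expect_error(correlation_screen(as.data.frame(X[1:2, ]), lai[1:2]),
               "at least 3")
})

test_that("projection chains maximize residual norms", {
  set.seed(2)
  # mutually orthogonal columns with distinct norms: selection order follows
  # residual norm, reproduced by an explicit Gram-Schmidt enumeration
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:4]
  X <- Q %*% diag(c(3, 9, 5, 7))
  chain <- spa_chain(X, start_column = 1, kmax = 4)
  expect_equal(chain, c(1, 2, 4, 3))   # start, then by descending norm
  # a duplicated column never enters twice
  Xd <- cbind(X, X[, 2])
  chain_d <- spa_chain(Xd, start_column = 2, kmax = 5)
  expect_false(all(c(2, 5) %in% chain_d))
  # kmax = 1 returns the start alone
  expect_equal(spa_chain(X, 3, kmax = 1), 3)
  # after selection, selected columns lie in the span of the chain
  set.seed(4)
  Xr <- scale(matrix(rnorm(30 * 8), 30, 8))
  ch <- spa_chain(Xr, 1, kmax = 5)
  Qb <- qr.Q(qr(Xr[, ch]))
  for (j in ch) {
    resid <- Xr[, j] - Qb %*% crossprod(Qb, Xr[, j])
    expect_lt(sqrt(sum(resid^2)), 1e-9)
  }
})

test_that("subset selection matches exhaustive search on a small toy", {
  set.seed(6)
  n <- 12
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- 1.5 * X[, 2] - X[, 5] + rnorm(n, 0, 0.05)
  got <- spa_select(as.data.frame(X), y, kmax = 4, folds = 3, seed = 7)
  want <- oracle_spa(X, y, kmax = 4, folds = 3, seed = 7)
  expect_equal(got$chosen_columns, colnames(X)[want$cols])
  expect_equal(got$rmsecv, want$rmse, tolerance = 1e-9)
  expect_true(all(c("v2", "v5") %in% got$chosen_columns))
})

test_that("a perfect linear predictor is recovered with near-zero RMSECV", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("c", 1:6)))
  y <- 2 * X[, 3] + 1
  res <- spa_select(as.data.frame(X), y, kmax = 4, folds = 5, seed = 1)
  expect_true("c3" %in% res$chosen_columns)
  expect_lt(res$rmsecv, 1e-8)
  # determinism
  res2 <- spa_select(as.data.frame(X), y, kmax = 4, folds = 5, seed = 1)
  expect_identical(res[c("start_column", "chain", "chosen_k", "chosen_columns")],
                   res2[c("start_column", "chain", "chosen_k", "chosen_columns")])
  # invariants: no duplicates, chosen_k is the path minimizer
  expect_equal(anyDuplicated(res$chain), 0L)
  expect_equal(res$chosen_k, which.min(res$rmsecv_path))
  expect_true(all(res$chosen_columns %in% colnames(X)))
})
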