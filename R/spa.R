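#' Pearson correlation screen of features against LAI
#'
#' Per-column Pearson r with two-sided p-values (t reference distribution)
#' and significance flags at 0.05 and 0.01; zero-variance columns are flagged
#' and report NA. When the table carries feature-family tags, a per-family
#' mean |r| summary is attached.
#'
#' @param table a `feature_table` (or plain data.frame/matrix of features).
#' @param lai measured LAI vector, one value per row.
#' @return a `correlation_screen` data.frame: `feature`, `family`, `r`, `p`,
#'   `sig05`, `sig01`, `zero_variance`; attribute `family_mean_abs_r`.
#' @export
correlation_screen <- function(table, lai) {
  X <- as.matrix(table[, setdiff(colnames(table), c("plot_id", "stage")),
                       drop = FALSE])
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (length(lai) != n) stop("lai length must match rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  zero_var <- sds < 1e-14
  r <- rep(NA_real_, ncol(X))
  r[!zero_var] <- suppressWarnings(as.vector(stats::cor(X[, !zero_var, drop = FALSE], lai)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fam <- feature_families(table)
  fam_col <- if (is.null(fam)) NA_character_ else unname(fam[colnames(X)])
  out <- data.frame(feature = colnames(X), family = fam_col, r = r, p = p,
                    sig05 = !is.na(p) & p < 0.05,
                    sig01 = !is.na(p) & p < 0.01,
                    zero_variance = zero_var,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(fam)) {
    attr(out, "family_mean_abs_r") <-
      tapply(abs(out$r), out$family, mean, na.rm = TRUE)
  }
  class(out) <- c("correlation_screen", class(out))
  out
}

#' Successive-projections chain from one start column
#'
#' Starting from `start_column`, iteratively projects every unselected column
#' onto the orthogonal complement of the span of the selected ones and
#' appends the column with the largest residual norm; the classic collinearity-
#' minimizing forward chain. Stops after `kmax` selections or when all
#' residual norms are numerically zero (collinear remainder).
#'
#' @param X numeric matrix with column-standardized variables.
#' @param start_column index of the first selected column.
#' @param kmax maximum chain length (default `min(ncol, nrow - 1)`).
#' @return integer vector of selected column indices, in selection order.
#' @export
spa_chain <- function(X, start_column, kmax = min(ncol(X), nrow(X) - 1)) {
  p <- ncol(X)
  if (start_column < 1 || start_column > p) stop("invalid start column", call. = FALSE)
  kmax <- min(kmax, p, nrow(X) - 1)
  R <- X
  chain <- integer(0)
  j <- start_column
  for (k in seq_len(kmax)) {
    nrm <- sqrt(sum(R[, j]^2))
    if (nrm < 1e-9) break
    chain <- c(chain, j)
    qv <- R[, j] / nrm
    R <- R - qv %*% crossprod(qv, R)     # project out the new direction
    if (k == kmax) break
    norms <- colSums(R^2)
    norms[chain] <- -Inf
    j <- which.max(norms)
    if (norms[j] < 1e-18) break
  }
  chain
}

# Cross-validated RMSE of an MLR fit on each prefix of a chain, averaged
# over one or more fold assignments (columns of `folds_idx`).
# Returns a numeric vector rmse[k], k = 1..length(chain).
rmsecv_prefixes <- function(X, y, chain, folds_idx) {
  folds_idx <- as.matrix(folds_idx)
  paths <- vapply(seq_len(ncol(folds_idx)), function(rr)
    rmsecv_prefixes_once(folds_idx[, rr], X, y, chain), numeric(length(chain)))
  rowMeans(matrix(paths, nrow = length(chain)))
}

rmsecv_prefixes_once <- function(folds_idx, X, y, chain) {
  kmax <- length(chain)
  n <- length(y)
  sq_err <- matrix(NA_real_, n, kmax)
  for (f in sort(unique(folds_idx))) {
    te <- which(folds_idx == f)
    tr <- which(folds_idx != f)
    Xtr <- X[tr, chain, drop = FALSE]
    Xte <- X[te, chain, drop = FALSE]
    ytr <- y[tr]
    for (k in seq_len(kmax)) {
      fit <- stats::.lm.fit(cbind(1, Xtr[, seq_len(k), drop = FALSE]), ytr)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      pred <- cbind(1, Xte[, seq_len(k), drop = FALSE]) %*% cf
      sq_err[te, k] <- (y[te] - pred)^2
    }
  }
  sqrt(colMeans(sq_err))
}

#' SPA variable selection with cross-validated chain length
#'
#' Runs [spa_chain()] from every candidate start column (exhaustive starts,
#' removing the start-point randomness of the original algorithm); for each
#' chain prefix of length 1..`kmax`, estimates RMSE of k-fold cross-validated
#' multiple linear regression (SPA-MLR); returns the `(start, k)` pair
#' minimizing RMSECV, first minimum on ties. Columns are standardized to zero
#' mean / unit variance before projection; zero-variance columns are excluded
#' from the candidate set.
#'
#' @param table a `feature_table`, data.frame or matrix of candidate features.
#' @param lai response vector.
#' @param kmax maximum subset size (default `min(30, floor(n/3))`).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param starts candidate start columns (default: all usable columns).
#' @param cv_repeats number of repeated fold assignments whose RMSECV paths
#'   are averaged (default 3); repetition stabilizes the chain-length choice
#'   when many candidate chains compete.
#' @return an `spa_result`: list with `start_column`, `chain` (indices into
#'   the usable columns of the input), `rmsecv_path`, `chosen_k`,
#'   `chosen_columns` (names), `columns` (candidate names).
#' @export
spa_select <- function(table, lai, kmax = NULL, folds = 5L, seed = 0L,
                       starts = NULL, cv_repeats = 3L) {
  X0 <- as.matrix(table[, setdiff(colnames(table), c("plot_id", "stage")),
                        drop = FALSE])
  n <- nrow(X0)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (n < 2 * folds) stop("too few samples for the requested folds", call. = FALSE)
  kmax <- kmax %||% min(30L, floor(n / 3))
  kmax <- min(kmax, ncol(X0), n - 2)
  sds <- apply(X0, 2, stats::sd)
  usable <- which(sds > 1e-14)
  X <- scale(X0[, usable, drop = FALSE])
  colnames(X) <- colnames(X0)[usable]
  if (is.null(starts)) starts <- seq_len(ncol(X))
  folds_idx <- vapply(seq_len(cv_repeats), function(rep_i) {
    set.seed(derive_seed(seed, 53L, rep_i))
    sample(rep(seq_len(folds), length.out = n))
  }, integer(n))
  y <- as.numeric(lai)

  best <- list(rmse = Inf)
  for (s in starts) {
    chain <- spa_chain(X, s, kmax)
    if (!length(chain)) next
    path <- rmsecv_prefixes(X, y, chain, folds_idx)
    k <- which.min(path)               # which.min takes the first minimum
    if (path[k] < best$rmse - 1e-15) {
      best <- list(rmse = path[k], start = s, chain = chain, path = path, k = k)
    }
  }
  if (!is.finite(best$rmse)) stop("SPA failed: no usable chain", call. = FALSE)
  structure(list(start_column = best$start,
                 chain = best$chain,
                 rmsecv_path = best$path,
                 chosen_k = best$k,
                 rmsecv = best$rmse,
                 chosen_columns = colnames(X)[best$chain[seq_len(best$k)]],
                 columns = colnames(X)),
            class = "spa_result")
}

#' @export
print.spa_result <- function(x, ...) {
  cat(sprintf("SPA selection: %d of %d columns (start %s, RMSECV %.4f)\n",
              x$chosen_k, length(x$columns), x$columns[x$start_column], x$rmsecv))
  cat("  ", paste(x$chosen_columns, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an SPA result as JSON
#' @param result an `spa_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spa_result <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
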