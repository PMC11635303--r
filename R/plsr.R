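#' Partial least squares regression (SIMPLS)
#'
#' Univariate-response SIMPLS with internally standardized predictors and a
#' centered response. The number of latent components defaults to the
#' minimizer of 5-fold cross-validated RMSE over 1..`max_ncomp`.
#'
#' @param X predictor matrix (n x p).
#' @param y response vector.
#' @param ncomp fixed number of components; `NULL` (default) selects by CV.
#' @param max_ncomp upper bound for CV selection (default 10, capped by rank).
#' @param folds CV folds (default 5).
#' @param seed seed for the CV fold assignment.
#' @return a `plsr_fit` with `coefficients` (p x ncomp path, original scale),
#'   `intercepts`, `ncomp`, `cv_rmse`.
#' @export
fit_plsr <- function(X, y, ncomp = NULL, max_ncomp = 10L, folds = 5L, seed = 0L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y) || n < 5) stop("need matching X rows and >= 5 samples", call. = FALSE)
  amax <- min(max_ncomp, p, n - 1)
  cv_rmse <- NULL
  if (is.null(ncomp)) {
    set.seed(derive_seed(seed, 71L))
    fidx <- sample(rep(seq_len(folds), length.out = n))
    sq <- matrix(NA_real_, n, amax)
    for (f in seq_len(folds)) {
      te <- fidx == f
      fit <- simpls_core(X[!te, , drop = FALSE], y[!te], amax)
      pred <- sweep(X[te, , drop = FALSE] %*% fit$B, 2, fit$b0, "+")
      sq[te, seq_len(ncol(pred))] <- (y[te] - pred)^2
    }
    cv_rmse <- sqrt(colMeans(sq, na.rm = TRUE))
    ncomp <- which.min(cv_rmse)
  }
  ncomp <- min(ncomp, amax)
  fit <- simpls_core(X, y, ncomp)
  structure(list(coefficients = fit$B, intercepts = fit$b0, ncomp = ncomp,
                 cv_rmse = cv_rmse, colnames = colnames(X)),
            class = "plsr_fit")
}

# SIMPLS with standardized X and centered y; returns original-scale
# coefficient path B (p x A) and intercepts b0 (length A).
simpls_core <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  mx <- colMeans(X)
  sx <- apply(X, 2, stats::sd)
  sx[sx < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y)
  yc <- y - my
  A <- min(A, p, n - 1)
  S <- crossprod(Xs, yc)
  Rw <- matrix(0, p, A); Q <- numeric(A); V <- matrix(0, p, A)
  a_eff <- 0
  for (a in seq_len(A)) {
    r <- S
    t <- Xs %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) break
    t <- t / nt; r <- r / nt
    pl <- crossprod(Xs, t)
    Q[a] <- sum(yc * t)
    v <- pl
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pl)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    V[, a] <- v
    Rw[, a] <- r
    S <- S - v %*% crossprod(v, S)
    a_eff <- a
  }
  if (a_eff == 0) stop("PLSR: degenerate predictors", call. = FALSE)
  Bs <- vapply(seq_len(a_eff), function(k)
    as.vector(Rw[, seq_len(k), drop = FALSE] %*% Q[seq_len(k)]), numeric(p))
  Bs <- matrix(Bs, nrow = p)
  B <- Bs / sx                            # back to original X scale
  b0 <- my - as.vector(crossprod(B, mx))
  list(B = B, b0 = b0)
}

#' @export
predict.plsr_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$colnames)) X <- X[, object$colnames, drop = FALSE]
  ncomp <- min(ncomp, ncol(object$coefficients))
  as.vector(X %*% object$coefficients[, ncomp] + object$intercepts[ncomp])
}
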