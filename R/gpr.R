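#' Gaussian process regression (squared-exponential kernel, ARD)
#'
#' GP regression with an automatic-relevance-determination squared-exponential
#' kernel plus an additive noise term:
#'
#'   k(x, x') = sf2 * exp(-0.5 * sum_d (x_d - x'_d)^2 / l_d^2) + sn2 * 1(x = x')
#'
#' Inputs are standardized and the output centered and scaled internally.
#' Hyperparameters (per-dimension length-scales `l_d`, signal variance `sf2`,
#' noise variance `sn2`) are set by maximizing the log marginal likelihood
#' (L-BFGS-B on log parameters with analytic gradients, two deterministic
#' starts). The per-dimension length-scales let the posterior down-weight
#' uninformative features, the standard practice for canopy-trait retrieval.
#'
#' @param X predictor matrix (n x p).
#' @param y response vector.
#' @param ard use per-dimension length-scales (default TRUE); FALSE fits one
#'   shared (isotropic) length-scale.
#' @param seed unused (fit is deterministic); kept for interface symmetry.
#' @return a `gpr_fit`.
#' @export
fit_gpr <- function(X, y, ard = TRUE, seed = 0L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y) || n < 5) stop("need matching X rows and >= 5 samples", call. = FALSE)
  mx <- colMeans(X)
  sx <- apply(X, 2, stats::sd); sx[sx < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y); sy <- stats::sd(y)
  if (sy < 1e-12) sy <- 1
  ys <- (y - my) / sy

  # per-dimension squared differences, n^2 x p
  D2d <- matrix(0, n * n, p)
  for (d in seq_len(p)) D2d[, d] <- as.vector(outer(Xs[, d], Xs[, d], "-")^2)
  nl <- if (ard) p else 1L
  dsum <- function(log_l) {
    l2 <- exp(2 * log_l)
    if (ard) matrix(D2d %*% (1 / l2), n, n) else matrix(rowSums(D2d), n, n) / l2
  }

  # theta = (log l (nl), log sf, log sn)
  obj <- function(theta) {
    D2w <- dsum(theta[seq_len(nl)])
    sf2 <- exp(2 * theta[nl + 1]); sn2 <- exp(2 * theta[nl + 2])
    Kse <- sf2 * exp(-0.5 * D2w)
    K <- Kse + diag(sn2 + 1e-8, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10, grad = rep(0, length(theta))))
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    nll <- 0.5 * sum(ys * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
    Kinv <- chol2inv(ch)
    W <- Kinv - tcrossprod(alpha)        # d(nll)/dK = W/2
    grad <- numeric(length(theta))
    if (ard) {
      l2 <- exp(2 * theta[seq_len(nl)])
      WK <- W * Kse
      for (d in seq_len(nl)) {
        dD <- matrix(D2d[, d], n, n)
        grad[d] <- 0.5 * sum(WK * dD) / l2[d]   # dK/dlog l_d = Kse * dD / l_d^2
      }
    } else {
      WK <- W * Kse
      grad[1] <- 0.5 * sum(WK * D2w)
    }
    grad[nl + 1] <- sum(W * Kse)               # dK/dlog sf = 2 Kse
    grad[nl + 2] <- sum(diag(W)) * sn2         # dK/dlog sn = 2 sn2 I
    list(value = nll, grad = grad)
  }
  fn <- function(theta) obj(theta)$value
  gr <- function(theta) obj(theta)$grad

  med <- stats::median(sqrt(rowSums(D2d)))
  if (!is.finite(med) || med <= 0) med <- 1
  starts <- list(c(rep(log(med), nl), 0, log(0.3)),
                 c(rep(log(med / 4), nl), 0, log(0.1)))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, fn, gr, method = "L-BFGS-B",
                   lower = c(rep(log(med) - 6, nl), -4, log(1e-3)),
                   upper = c(rep(log(med) + 6, nl), 3, 1),
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("GPR hyperparameter optimization failed", call. = FALSE)
  theta <- best$par
  l2 <- exp(2 * theta[seq_len(nl)])
  sf2 <- exp(2 * theta[nl + 1]); sn2 <- exp(2 * theta[nl + 2])
  D2w <- dsum(theta[seq_len(nl)])
  K <- sf2 * exp(-0.5 * D2w) + diag(sn2 + 1e-8, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  structure(list(Xs = Xs, alpha = alpha, l2 = l2, sf2 = sf2, sn2 = sn2,
                 ard = ard, mx = mx, sx = sx, my = my, sy = sy,
                 log_marginal = -best$value, colnames = colnames(X)),
            class = "gpr_fit")
}

#' @export
predict.gpr_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$colnames)) X <- X[, object$colnames, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$mx), 2, object$sx, "/")
  p <- ncol(Xs)
  l <- if (object$ard) sqrt(object$l2) else rep(sqrt(object$l2), p)
  A <- sweep(Xs, 2, l, "/")
  B <- sweep(object$Xs, 2, l, "/")
  d2 <- pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B), 0)
  Ks <- object$sf2 * exp(-0.5 * d2)
  as.vector(Ks %*% object$alpha) * object$sy + object$my
}
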