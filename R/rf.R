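#' Random forest regression
#'
#' CART-style regression forest: `ntree` trees grown on bootstrap samples,
#' each split searching `mtry` randomly drawn predictors for the
#' variance-minimizing threshold; nodes with `nodesize` or fewer samples
#' become leaves predicting their mean. Defaults follow the standard rule for
#' regression: `ntree = 500`, `mtry = max(1, floor(p/3))`.
#'
#' @param X predictor matrix (n x p).
#' @param y response vector.
#' @param ntree number of trees (default 500).
#' @param mtry predictors tried per split (default `floor(p/3)`, at least 1).
#' @param nodesize minimum node size to attempt a split (default 5).
#' @param seed integer seed; fixed seed gives identical forests.
#' @return an `rfr_fit` (list of trees plus metadata).
#' @export
fit_rfr <- function(X, y, ntree = 500L, mtry = NULL, nodesize = 5L, seed = 0L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y) || n < 5) stop("need matching X rows and >= 5 samples", call. = FALSE)
  mtry <- mtry %||% max(1L, floor(p / 3))
  mtry <- min(mtry, p)
  set.seed(derive_seed(seed, 89L))
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(X, y, boot, mtry, nodesize)
  }
  structure(list(trees = trees, mtry = mtry, ntree = ntree,
                 colnames = colnames(X)),
            class = "rfr_fit")
}

# Grow one regression tree on the rows `idx` (with multiplicity).
# Node table columns: var (0 = leaf), split, left, right, value.
grow_tree <- function(X, y, idx, mtry, nodesize) {
  var_v <- integer(0); split_v <- numeric(0)
  left_v <- integer(0); right_v <- integer(0); value_v <- numeric(0)
  new_node <- function() {
    var_v[length(var_v) + 1L] <<- 0L
    split_v[length(split_v) + 1L] <<- NA_real_
    left_v[length(left_v) + 1L] <<- 0L
    right_v[length(right_v) + 1L] <<- 0L
    value_v[length(value_v) + 1L] <<- NA_real_
    length(var_v)
  }
  root <- new_node()
  stack <- list(list(node = root, idx = idx))
  p <- ncol(X)
  while (length(stack)) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- item$node; rows <- item$idx
    yv <- y[rows]
    value_v[node] <- mean(yv)
    if (length(rows) <= nodesize || stats::var(yv) < 1e-24) next
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    best <- find_best_split(X, yv, rows, feats)
    if (is.null(best)) next
    go_left <- X[rows, best$var] <= best$split
    l <- new_node(); r <- new_node()
    var_v[node] <- best$var; split_v[node] <- best$split
    left_v[node] <- l; right_v[node] <- r
    stack[[length(stack) + 1L]] <- list(node = l, idx = rows[go_left])
    stack[[length(stack) + 1L]] <- list(node = r, idx = rows[!go_left])
  }
  list(var = var_v, split = split_v, left = left_v, right = right_v,
       value = value_v)
}

# Variance-minimizing split over the candidate features; O(n log n) per
# feature via sorted cumulative sums. Returns NULL if no split separates
# distinct values.
find_best_split <- function(X, yv, rows, feats) {
  n <- length(rows)
  best_gain <- 0; best <- NULL
  base <- sum(yv)^2 / n
  for (f in feats) {
    xv <- X[rows, f]
    ord <- order(xv)
    xs <- xv[ord]; ys <- yv[ord]
    cs <- cumsum(ys)
    nl <- seq_len(n - 1)
    valid <- xs[nl] < xs[nl + 1L]         # split only between distinct values
    if (!any(valid)) next
    gain <- cs[nl]^2 / nl + (cs[n] - cs[nl])^2 / (n - nl) - base
    gain[!valid] <- -Inf
    k <- which.max(gain)
    if (gain[k] > best_gain + 1e-12) {
      best_gain <- gain[k]
      best <- list(var = f, split = (xs[k] + xs[k + 1L]) / 2)
    }
  }
  best
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  groups <- list(list(node = 1L, rows = seq_len(n)))
  while (length(groups)) {
    g <- groups[[length(groups)]]
    groups[[length(groups)]] <- NULL
    node <- g$node
    if (tree$var[node] == 0L) {
      out[g$rows] <- tree$value[node]
      next
    }
    go_left <- X[g$rows, tree$var[node]] <= tree$split[node]
    if (any(go_left)) {
      groups[[length(groups) + 1L]] <- list(node = tree$left[node],
                                            rows = g$rows[go_left])
    }
    if (any(!go_left)) {
      groups[[length(groups) + 1L]] <- list(node = tree$right[node],
                                            rows = g$rows[!go_left])
    }
  }
  out
}

#' @export
predict.rfr_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$colnames)) X <- X[, object$colnames, drop = FALSE]
  preds <- vapply(object$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}
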