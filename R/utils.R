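#' @useDynLib canopylai, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor pt rnorm runif sd var aggregate optim predict
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic mixing keeps every random draw in the pipeline traceable to
#' one master seed while giving independent streams to stages and plots.
#' Result is kept inside the 32-bit integer range R requires of `set.seed()`.
#'
#' @param master integer master seed.
#' @param ... one or more integer stream identifiers.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  ids <- c(...)
  s <- as.double(master) %% 2147483647
  for (id in ids) {
    s <- (s * 48271 + as.double(id) + 1) %% 2147483647
  }
  as.integer(s)
}

stopifnot_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
}

#' Point-in-polygon test for planar rings
#'
#' Even-odd ray casting. Points exactly on an edge are treated as inside,
#' which keeps pixel-center containment stable for axis-aligned plot
#' boundaries.
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param ring two-column matrix of ring vertices (closed or open).
#' @return logical vector.
#' @export
points_in_ring <- function(px, py, ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # edge inclusivity for axis-aligned segments (pixel centers on a boundary)
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if (xi == xj) {
      on_edge <- on_edge | (px == xi & py >= min(yi, yj) & py <= max(yi, yj))
    } else if (yi == yj) {
      on_edge <- on_edge | (py == yi & px >= min(xi, xj) & px <= max(xi, xj))
    }
    j <- i
  }
  inside | on_edge
}
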