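#' First principal-component image of a cube
#'
#' Covariance PCA on the per-pixel spectra of the valid pixels: each band is
#' mean-centered (no variance scaling), the covariance eigendecomposition is
#' taken, and the PC1 score image is returned together with its explained
#' variance ratio (largest eigenvalue over the trace). The loading's sign is
#' fixed so its largest-magnitude element is positive.
#'
#' @param cube a `reflectance_cube`.
#' @return a `pc_image`: list with `values` (H x W matrix, NA outside the
#'   mask), `explained_variance_ratio`, `loading`, `mask`.
#' @export
pca_first_component <- function(cube) {
  d <- dim(cube$values)
  if (d[3] < 2) stop("need at least 2 bands", call. = FALSE)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  valid <- as.vector(cube$mask)
  if (sum(valid) < 2) stop("need at least 2 valid pixels", call. = FALSE)
  X <- flat[valid, , drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  covm <- crossprod(Xc) / (nrow(Xc) - 1)
  tr <- sum(diag(covm))
  if (tr <= 0) stop("degenerate cube: zero spectral variance", call. = FALSE)
  eig <- eigen(covm, symmetric = TRUE)
  v <- eig$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  scores <- as.vector(Xc %*% v)
  img <- matrix(NA_real_, d[1], d[2])
  img[valid] <- scores
  structure(list(values = img,
                 explained_variance_ratio = eig$values[1] / tr,
                 loading = v, mask = cube$mask),
            class = "pc_image")
}

#' Quantize an image to G gray levels
#'
#' Linear stretch between the 2nd and 98th percentile of the valid pixels,
#' mapped to integer levels 0..G-1 with clipping. A constant image maps to
#' level 0 everywhere.
#'
#' @param image numeric matrix (NA allowed).
#' @param G number of gray levels (>= 2).
#' @param mask optional logical matrix; masked-out or NA pixels become NA.
#' @param probs stretch percentiles (default `c(0.02, 0.98)`).
#' @return integer matrix of levels in 0..G-1, NA where invalid.
#' @export
quantize <- function(image, G = 32L, mask = NULL, probs = c(0.02, 0.98)) {
  if (G < 2) stop("G must be >= 2", call. = FALSE)
  valid <- is.finite(image)
  if (!is.null(mask)) valid <- valid & mask
  out <- matrix(NA_integer_, nrow(image), ncol(image))
  vals <- image[valid]
  if (!length(vals)) return(out)
  q <- stats::quantile(vals, probs, names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    out[valid] <- 0L
    return(out)
  }
  lev <- floor((image[valid] - q[1]) / (q[2] - q[1]) * G)
  out[valid] <- as.integer(pmin(pmax(lev, 0), G - 1))
  out
}

#' Gray-level co-occurrence matrix of one window
#'
#' Counts co-occurrences of `(q[r, c], q[r + offset[1], c + offset[2]])` over
#' all pixel pairs lying inside the window, optionally symmetrized (pair
#' counted in both orders), normalized to probabilities. The default offset
#' `(-1, +1)` is the 45-degree direction at distance 1.
#'
#' @param q integer window (levels 0..G-1; NA = masked).
#' @param G number of gray levels.
#' @param offset integer `(row delta, col delta)`.
#' @param symmetric accumulate both pair orders (default TRUE).
#' @return a `glcm` object: list with `p` (G x G probabilities), `levels`,
#'   `offset`, `symmetric`, `n_pairs`.
#' @export
glcm_window <- function(q, G = 32L, offset = c(-1L, 1L), symmetric = TRUE) {
  if (anyNA(q)) stop("window contains masked pixels", call. = FALSE)
  nr <- nrow(q); nc <- ncol(q)
  p <- matrix(0, G, G)
  n_pairs <- 0L
  for (r in seq_len(nr)) {
    r2 <- r + offset[1]
    if (r2 < 1 || r2 > nr) next
    for (cc in seq_len(nc)) {
      c2 <- cc + offset[2]
      if (c2 < 1 || c2 > nc) next
      i <- q[r, cc] + 1L; j <- q[r2, c2] + 1L
      p[i, j] <- p[i, j] + 1
      if (symmetric) p[j, i] <- p[j, i] + 1
      n_pairs <- n_pairs + 1L
    }
  }
  if (n_pairs == 0) stop("window too small for the offset", call. = FALSE)
  structure(list(p = p / sum(p), levels = G, offset = offset,
                 symmetric = symmetric, n_pairs = n_pairs),
            class = "glcm")
}

glcm_marginals <- function(m) {
  px <- rowSums(m$p); py <- colSums(m$p)
  G <- m$levels
  i <- 0:(G - 1)
  list(px = px, py = py, i = i,
       mux = sum(i * px), muy = sum(i * py),
       sdx = sqrt(sum((i - sum(i * px))^2 * px)),
       sdy = sqrt(sum((i - sum(i * py))^2 * py)))
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Simple Haralick features (8) of a GLCM
#'
#' Energy, Entropy (natural log), Correlation, Inverse difference moment,
#' Inertia (contrast), Cluster shade, Cluster prominence, and Haralick
#' correlation in the Orfeo Toolbox convention
#' `(sum_ij i*j*p - mu_t^2) / sigma_t^2` with `mu_t`, `sigma_t` from the row
#' marginal. Degenerate (zero-variance) matrices report both correlations as
#' 0 and carry a `degenerate` attribute.
#'
#' @param m a `glcm`.
#' @return named numeric vector of length 8.
#' @export
haralick_simple <- function(m) {
  p <- m$p
  G <- m$levels
  mg <- glcm_marginals(m)
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  energy <- sum(p^2)
  entropy <- -sum(xlogx(p))
  inertia <- sum((i - j)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  degenerate <- mg$sdx < 1e-12 || mg$sdy < 1e-12
  corr <- if (degenerate) 0 else sum((i - mg$mux) * (j - mg$muy) * p) / (mg$sdx * mg$sdy)
  shade <- sum((i + j - mg$mux - mg$muy)^3 * p)
  prom <- sum((i + j - mg$mux - mg$muy)^4 * p)
  hcorr <- if (degenerate) 0 else (sum(i * j * p) - mg$mux^2) / (mg$sdx^2)
  out <- c(Energy = energy, Entropy = entropy, Correlation = corr,
           InverseDifferenceMoment = idm, Inertia = inertia,
           ClusterShade = shade, ClusterProminence = prom,
           HaralickCorrelation = hcorr)
  attr(out, "degenerate") <- degenerate
  out
}

#' Advanced Haralick features (10) of a GLCM
#'
#' Mean, Sum of squares: variance, Dissimilarity, Sum average / variance /
#' entropy and Difference variance / entropy from the diagonal marginals
#' `p_{x+y}` and `p_{x-y}`, and the two information measures of correlation
#' IC1 = (HXY - HXY1)/max(HX, HY), IC2 = sqrt(1 - exp(-2 (HXY2 - HXY))).
#' All entropies use the natural logarithm with 0 log 0 := 0.
#'
#' @param m a `glcm`.
#' @return named numeric vector of length 10.
#' @export
haralick_advanced <- function(m) {
  p <- m$p
  G <- m$levels
  mg <- glcm_marginals(m)
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  mean_f <- sum(i * p)
  variance <- sum((i - mean_f)^2 * p)
  dissim <- sum(abs(i - j) * p)
  # diagonal marginals
  psum <- vapply(0:(2 * G - 2), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(G - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 0:(2 * G - 2); kd <- 0:(G - 1)
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- -sum(xlogx(psum))
  diff_avg <- sum(kd * pdiff)
  diff_var <- sum((kd - diff_avg)^2 * pdiff)
  diff_ent <- -sum(xlogx(pdiff))
  hx <- -sum(xlogx(mg$px)); hy <- -sum(xlogx(mg$py))
  hxy <- -sum(xlogx(p))
  pp <- outer(mg$px, mg$py)
  hxy1 <- -sum(ifelse(p > 0 & pp > 0, p * log(pp), 0))
  hxy2 <- -sum(xlogx(pp))
  degenerate <- max(hx, hy) < 1e-12
  ic1 <- if (degenerate) 0 else (hxy - hxy1) / max(hx, hy)
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  out <- c(Mean = mean_f, Variance = variance, Dissimilarity = dissim,
           SumAverage = sum_avg, SumVariance = sum_var, SumEntropy = sum_ent,
           DifferenceVariance = diff_var, DifferenceEntropy = diff_ent,
           IC1 = ic1, IC2 = ic2)
  attr(out, "degenerate") <- degenerate
  out
}

#' Gray-level run-length matrix of one window (45-degree direction)
#'
#' Traces maximal runs of equal gray level along each 45-degree (up-right)
#' diagonal of the window; `r[g, l]` counts runs of level `g` (row `g + 1`)
#' and length `l`.
#'
#' @param q integer window (levels 0..G-1; NA = masked).
#' @param G number of gray levels.
#' @return a `glrlm`: list with `r` (G x Lmax counts), `Np` (pixels in the
#'   window), `Nr` (total runs), `direction` (45).
#' @export
glrlm_window <- function(q, G = 32L) {
  if (anyNA(q)) stop("window contains masked pixels", call. = FALSE)
  nr <- nrow(q); nc <- ncol(q)
  lmax <- min(nr, nc)
  r <- matrix(0, G, lmax)
  # 45-degree (up-right) diagonals: constant r + c
  for (s in 2:(nr + nc)) {
    rows <- seq(min(nr, s - 1), max(1, s - nc))   # bottom-left to top-right
    len <- 0L; lev <- NA_integer_
    for (rr in rows) {
      v <- q[rr, s - rr]
      if (!is.na(lev) && v == lev) {
        len <- len + 1L
      } else {
        if (len > 0) r[lev + 1L, len] <- r[lev + 1L, len] + 1
        lev <- v; len <- 1L
      }
    }
    if (len > 0) r[lev + 1L, len] <- r[lev + 1L, len] + 1
  }
  structure(list(r = r, Np = nr * nc, Nr = sum(r), direction = 45),
            class = "glrlm")
}

#' Run-length texture features (10) of a run-length matrix
#'
#' Galloway conventions with run-length weights `l^2` and gray-level weights
#' `(g + 1)^2` (levels are 0-based, shifted by +1 so level 0 is weightable):
#' Short/Long run emphasis, Grey-level and Run-length nonuniformity, Run
#' percentage, Low/High grey-level run emphasis, Short run low/high and Long
#' run low grey-level emphasis.
#'
#' @param rlm a `glrlm`.
#' @return named numeric vector of length 10.
#' @export
runlength_features <- function(rlm) {
  r <- rlm$r
  Nr <- rlm$Nr
  if (Nr <= 0) stop("run-length matrix has no runs", call. = FALSE)
  G <- nrow(r); L <- ncol(r)
  g <- matrix(seq_len(G), G, L)          # g + 1 with 0-based levels
  l <- matrix(seq_len(L), G, L, byrow = TRUE)
  c(ShortRunEmphasis = sum(r / l^2) / Nr,
    LongRunEmphasis = sum(r * l^2) / Nr,
    GreyLevelNonuniformity = sum(rowSums(r)^2) / Nr,
    RunLengthNonuniformity = sum(colSums(r)^2) / Nr,
    RunPercentage = Nr / rlm$Np,
    LowGreyLevelRunEmphasis = sum(r / g^2) / Nr,
    HighGreyLevelRunEmphasis = sum(r * g^2) / Nr,
    ShortRunLowGreyLevelEmphasis = sum(r / (g^2 * l^2)) / Nr,
    ShortRunHighGreyLevelEmphasis = sum(r * g^2 / l^2) / Nr,
    LongRunLowGreyLevelEmphasis = sum(r * l^2 / g^2) / Nr)
}

#' Names of the 28 texture features, in published order
#' @return character vector of length 28 (without the `TEX_` prefix).
#' @export
texture_feature_names <- function() {
  c("Energy", "Entropy", "Correlation", "InverseDifferenceMoment", "Inertia",
    "ClusterShade", "ClusterProminence", "HaralickCorrelation",
    "Mean", "Variance", "Dissimilarity", "SumAverage", "SumVariance",
    "SumEntropy", "DifferenceVariance", "DifferenceEntropy", "IC1", "IC2",
    "ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
    "RunLengthNonuniformity", "RunPercentage", "LowGreyLevelRunEmphasis",
    "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
    "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis")
}

#' All 28 texture features of one window (R reference path)
#' @param q integer window (levels 0..G-1).
#' @param G number of gray levels.
#' @param offset GLCM offset (default 45-degree).
#' @return named numeric vector of length 28.
#' @export
window_texture_features <- function(q, G = 32L, offset = c(-1L, 1L)) {
  m <- glcm_window(q, G, offset)
  c(haralick_simple(m), haralick_advanced(m),
    runlength_features(glrlm_window(q, G)))
}

#' Per-pixel texture feature maps (sliding window)
#'
#' Computes all 28 features on a sliding `window x window` neighborhood
#' centered at each pixel (C++ backend). Windows that are not fully inside
#' the image or that contain any masked pixel are skipped (NA), with no
#' padding.
#'
#' @param q integer level matrix from [quantize()] (NA = masked).
#' @param G number of gray levels.
#' @param window odd window size (default 5).
#' @param offset GLCM offset (default `c(-1, 1)`, the 45-degree direction).
#' @return H x W x 28 array, dimnames on the feature axis.
#' @export
texture_maps <- function(q, G = 32L, window = 5L, offset = c(-1L, 1L)) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3", call. = FALSE)
  qm <- q
  qm[is.na(qm)] <- -1L
  storage.mode(qm) <- "integer"
  arr <- texture_maps_cpp(qm, as.integer(G), as.integer(window),
                          as.integer(offset[1]), as.integer(offset[2]))
  dimnames(arr) <- list(NULL, NULL, texture_feature_names())
  arr
}

#' Per-plot texture feature table
#'
#' Quantizes the PC1 image over its valid pixels, computes per-pixel feature
#' maps on sliding windows, and averages each feature over the map pixels
#' whose centers fall inside each plot polygon.
#'
#' @param pc1 a `pc_image` from [pca_first_component()].
#' @param layout a `plot_layout`.
#' @param G gray levels (default 32).
#' @param window window size (default 5).
#' @param offset GLCM offset (default 45-degree).
#' @param pixel_size ground sampling distance of the image, metres.
#' @param stage optional stage label for the key column.
#' @return a `feature_table` with `plot_id`, `stage` and 28 `TEX_*` columns.
#' @export
texture_feature_table <- function(pc1, layout, G = 32L, window = 5L,
                                  offset = c(-1L, 1L), pixel_size = 0.25,
                                  stage = NULL) {
  q <- quantize(pc1$values, G, mask = pc1$mask)
  maps <- texture_maps(q, G, window, offset)
  H <- nrow(q); W <- ncol(q)
  px_grid <- rep((seq_len(W) - 0.5) * pixel_size, each = H)
  py_grid <- rep((seq_len(H) - 0.5) * pixel_size, times = W)
  nfeat <- dim(maps)[3]
  flat <- matrix(maps, H * W, nfeat)
  out <- matrix(NA_real_, nrow(layout), nfeat)
  for (i in seq_len(nrow(layout))) {
    inside <- points_in_ring(px_grid, py_grid, layout$polygon[[i]])
    vals <- flat[inside, , drop = FALSE]
    ok <- stats::complete.cases(vals)
    if (!any(ok)) {
      stop(sprintf("plot %s has no computable texture windows", layout$plot_id[i]),
           call. = FALSE)
    }
    out[i, ] <- colMeans(vals[ok, , drop = FALSE])
  }
  colnames(out) <- paste0("TEX_", texture_feature_names())
  tab <- data.frame(plot_id = layout$plot_id,
                    stage = stage %||% NA_character_,
                    out, check.names = FALSE, stringsAsFactors = FALSE)
  attr(tab, "family") <- stats::setNames(rep("TEX", nfeat), colnames(out))
  class(tab) <- c("feature_table", class(tab))
  tab
}
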