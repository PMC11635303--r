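# Independent brute-force oracles. These are deliberately literal (double
# loops, no shared code with the package internals) so that agreement with
# the package implementations is evidence, not tautology.

# ---- GLCM construction oracle -------------------------------------------
oracle_glcm <- function(q, G, offset = c(-1L, 1L)) {
  counts <- matrix(0, G, G)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + offset[1]; c2 <- cc + offset[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        counts[q[r, cc] + 1, q[r2, c2] + 1] <- counts[q[r, cc] + 1, q[r2, c2] + 1] + 1
        counts[q[r2, c2] + 1, q[r, cc] + 1] <- counts[q[r2, c2] + 1, q[r, cc] + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# ---- Haralick feature oracles (literal sums over matrix cells) ----------
oracle_haralick <- function(p) {
  G <- nrow(p)
  px <- numeric(G); py <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    px[i] <- px[i] + p[i, j]; py[j] <- py[j] + p[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:G) { mux <- mux + (i - 1) * px[i]; muy <- muy + (i - 1) * py[i] }
  vx <- 0; vy <- 0
  for (i in 1:G) {
    vx <- vx + (i - 1 - mux)^2 * px[i]; vy <- vy + (i - 1 - muy)^2 * py[i]
  }
  energy <- 0; entropy <- 0; corr <- 0; idm <- 0; inertia <- 0
  shade <- 0; prom <- 0; sij <- 0; mean_f <- 0; variance <- 0; dissim <- 0
  hxy1 <- 0
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]
    ii <- i - 1; jj <- j - 1
    energy <- energy + v^2
    if (v > 0) entropy <- entropy - v * log(v)
    corr <- corr + (ii - mux) * (jj - muy) * v
    idm <- idm + v / (1 + (ii - jj)^2)
    inertia <- inertia + (ii - jj)^2 * v
    shade <- shade + (ii + jj - mux - muy)^3 * v
    prom <- prom + (ii + jj - mux - muy)^4 * v
    sij <- sij + ii * jj * v
    mean_f <- mean_f + ii * v
    dissim <- dissim + abs(ii - jj) * v
    if (v > 0 && px[i] * py[j] > 0) hxy1 <- hxy1 - v * log(px[i] * py[j])
  }
  for (i in 1:G) for (j in 1:G) {
    variance <- variance + (i - 1 - mean_f)^2 * p[i, j]
  }
  degen <- sqrt(vx) < 1e-12 || sqrt(vy) < 1e-12
  correlation <- if (degen) 0 else corr / (sqrt(vx) * sqrt(vy))
  hcorr <- if (degen) 0 else (sij - mux^2) / vx
  # diagonal marginals
  psum <- numeric(2 * G - 1); pdiff <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  sum_avg <- 0
  for (k in seq_along(psum)) sum_avg <- sum_avg + (k - 1) * psum[k]
  sum_var <- 0; sum_ent <- 0
  for (k in seq_along(psum)) {
    sum_var <- sum_var + (k - 1 - sum_avg)^2 * psum[k]
    if (psum[k] > 0) sum_ent <- sum_ent - psum[k] * log(psum[k])
  }
  diff_avg <- 0
  for (k in seq_along(pdiff)) diff_avg <- diff_avg + (k - 1) * pdiff[k]
  diff_var <- 0; diff_ent <- 0
  for (k in seq_along(pdiff)) {
    diff_var <- diff_var + (k - 1 - diff_avg)^2 * pdiff[k]
    if (pdiff[k] > 0) diff_ent <- diff_ent - pdiff[k] * log(pdiff[k])
  }
  hx <- 0; hy <- 0; hxy2 <- 0
  for (i in 1:G) {
    if (px[i] > 0) hx <- hx - px[i] * log(px[i])
    if (py[i] > 0) hy <- hy - py[i] * log(py[i])
  }
  for (i in 1:G) for (j in 1:G) {
    pp <- px[i] * py[j]
    if (pp > 0) hxy2 <- hxy2 - pp * log(pp)
  }
  ic1 <- if (max(hx, hy) < 1e-12) 0 else (entropy - hxy1) / max(hx, hy)
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(Energy = energy, Entropy = entropy, Correlation = correlation,
    InverseDifferenceMoment = idm, Inertia = inertia, ClusterShade = shade,
    ClusterProminence = prom, HaralickCorrelation = hcorr,
    Mean = mean_f, Variance = variance, Dissimilarity = dissim,
    SumAverage = sum_avg, SumVariance = sum_var, SumEntropy = sum_ent,
    DifferenceVariance = diff_var, DifferenceEntropy = diff_ent,
    IC1 = ic1, IC2 = ic2)
}

# ---- run-length oracle ---------------------------------------------------
oracle_glrlm <- function(q, G) {
  nr <- nrow(q); nc <- ncol(q)
  runs <- list()
  for (s in 2:(nr + nc)) {
    path <- c()
    for (r in seq(nr, 1)) {
      cc <- s - r
      if (cc >= 1 && cc <= nc) path <- c(path, q[r, cc])
    }
    if (!length(path)) next
    start <- 1
    for (k in seq_along(path)) {
      if (k == length(path) || path[k + 1] != path[k]) {
        runs[[length(runs) + 1]] <- c(level = path[start], len = k - start + 1)
        start <- k + 1
      }
    }
  }
  r <- matrix(0, G, min(nr, nc))
  for (run in runs) r[run["level"] + 1, run["len"]] <- r[run["level"] + 1, run["len"]] + 1
  r
}

oracle_runlength_features <- function(r, Np) {
  Nr <- sum(r)
  sre <- 0; lre <- 0; gln <- 0; rln <- 0; lgre <- 0; hgre <- 0
  srlge <- 0; srhge <- 0; lrlge <- 0
  for (g in seq_len(nrow(r))) for (l in seq_len(ncol(r))) {
    v <- r[g, l]
    sre <- sre + v / l^2; lre <- lre + v * l^2
    lgre <- lgre + v / g^2; hgre <- hgre + v * g^2
    srlge <- srlge + v / (g^2 * l^2); srhge <- srhge + v * g^2 / l^2
    lrlge <- lrlge + v * l^2 / g^2
  }
  for (g in seq_len(nrow(r))) gln <- gln + sum(r[g, ])^2
  for (l in seq_len(ncol(r))) rln <- rln + sum(r[, l])^2
  c(ShortRunEmphasis = sre / Nr, LongRunEmphasis = lre / Nr,
    GreyLevelNonuniformity = gln / Nr, RunLengthNonuniformity = rln / Nr,
    RunPercentage = Nr / Np, LowGreyLevelRunEmphasis = lgre / Nr,
    HighGreyLevelRunEmphasis = hgre / Nr,
    ShortRunLowGreyLevelEmphasis = srlge / Nr,
    ShortRunHighGreyLevelEmphasis = srhge / Nr,
    LongRunLowGreyLevelEmphasis = lrlge / Nr)
}

# ---- vegetation-index oracle sheet (hand-transcribed, index-by-index) ----
oracle_vi_sheet <- function(refl, wl) {
  R <- function(x) {
    d <- abs(wl - x)
    refl[which(d <= min(d) + 1e-12)[1]]
  }
  list(
    DVI = R(890) - R(670),
    EVI = 2.5 * (R(800) - R(670)) / (R(800) + 6 * R(670) - 7.5 * R(450) + 1),
    EVI2 = 2.5 * (R(800) - R(670)) / (R(800) + 2.4 * R(670) + 1),
    GNDVI = (R(750) - R(550)) / (R(750) + R(550)),
    GI = R(554) / R(677),
    LCI = (R(850) - R(710)) / (R(850) + R(670))^0.5,
    MCARI = ((R(700) - R(670)) - 0.2 * (R(700) - R(550))) * (R(700) / R(670)),
    MSR = (R(800) / R(670) - 1) / (R(800) / R(670) + 1)^0.5,
    MSAVI = 0.5 * (2 * R(800) + 1 - ((2 * R(800) + 1)^2 - 8 * (R(800) - R(670)))^0.5),
    MTVI1 = 1.2 * (1.2 * (R(800) - R(550)) - 2.5 * (R(670) - R(550))),
    MTVI2 = 1.5 * (1.2 * (R(800) - R(500)) - 2.5 * (R(670) - R(550))) /
      (2 * (R(800) + 1)^2 - (6 * R(800) - 5 * R(670)^0.5) - 0.5)^0.5,
    NDVI = (R(800) - R(680)) / (R(800) + R(680)),
    NDRE = (R(790) - R(720)) / (R(790) + R(720)),
    NPCI = (R(670) - R(460)) / (R(670) + R(460)),
    NDI = (R(850) - R(710)) / (R(850) + R(680)),
    NRI = (R(570) - R(670)) / (R(570) + R(670)),
    OSAVI = 1.16 * (R(800) - R(670)) / (R(800) + R(670) + 0.16),
    PSRI = (R(680) - R(500)) / R(750),
    PSND = (R(800) - R(470)) / (R(800) + R(470)),
    PBI = R(810) / R(560),
    RVI = R(810) / R(660),
    RDVI = (R(800) - R(670)) / (R(800) + R(670))^0.5,
    RASI = R(760) / R(500),
    RVSI = (R(712) + R(752)) / 2 - R(732),
    SAVI = 1.5 * (R(800) - R(670)) / (R(800) + R(670) + 0.5),
    SPVI = 0.4 * (3.7 * (R(800) - R(670)) - 1.2 * abs(R(550) - R(670))),
    TVI = 0.5 * (120 * (R(750) - R(550)) - 200 * (R(670) - R(550))),
    TCARI = 3 * ((R(710) - R(680)) - 0.2 * (R(700) - R(560)) * (R(710) / R(680))),
    VARI = (R(555) - R(680)) / (R(555) + R(680) - R(480)),
    WDRVI = (0.1 * R(800) - R(670)) / (0.1 * R(800) + R(670))
  )
}

# ---- metrics oracle ------------------------------------------------------
oracle_metrics <- function(y, yhat) {
  n <- length(y)
  ybar <- sum(y) / n
  sse <- 0; sst <- 0
  for (i in seq_len(n)) {
    sse <- sse + (y[i] - yhat[i])^2
    sst <- sst + (y[i] - ybar)^2
  }
  rmse <- sqrt(sse / n)
  list(r2 = 1 - sse / sst, rmse = rmse, nrmse = 100 * rmse / ybar)
}

# ---- exhaustive SPA oracle ----------------------------------------------
# Gram-Schmidt chain (its own implementation) + lm()-based CV over every
# (start, prefix length), reproducing spa_select's fold-assignment seeds.
oracle_spa <- function(X, y, kmax, folds, seed, cv_repeats = 3) {
  X <- scale(X)
  n <- nrow(X)
  fidx <- sapply(seq_len(cv_repeats), function(rep_i) {
    set.seed(canopylai::derive_seed(seed, 53L, rep_i))
    sample(rep(seq_len(folds), length.out = n))
  })
  gs_chain <- function(start) {
    chain <- start
    basis <- X[, start, drop = FALSE] / sqrt(sum(X[, start]^2))
    for (step in seq_len(kmax - 1)) {
      best_norm <- -1; best_j <- 0
      for (j in seq_len(ncol(X))) {
        if (j %in% chain) next
        v <- X[, j]
        for (b in seq_len(ncol(basis))) v <- v - sum(v * basis[, b]) * basis[, b]
        nv <- sqrt(sum(v^2))
        if (nv > best_norm) { best_norm <- nv; best_j <- j }
      }
      if (best_norm < 1e-9) break
      chain <- c(chain, best_j)
      v <- X[, best_j]
      for (b in seq_len(ncol(basis))) v <- v - sum(v * basis[, b]) * basis[, b]
      basis <- cbind(basis, v / sqrt(sum(v^2)))
    }
    chain
  }
  cv_rmse <- function(cols) {
    rms <- numeric(ncol(fidx))
    for (rr in seq_len(ncol(fidx))) {
      sq <- numeric(n)
      for (f in 1:folds) {
        te <- fidx[, rr] == f
        d <- data.frame(y = y[!te], X[!te, cols, drop = FALSE])
        fit <- lm(y ~ ., data = d)
        pred <- predict(fit, newdata = data.frame(X[te, cols, drop = FALSE]))
        sq[te] <- (y[te] - pred)^2
      }
      rms[rr] <- sqrt(mean(sq))
    }
    mean(rms)
  }
  best <- list(rmse = Inf)
  for (s in seq_len(ncol(X))) {
    chain <- gs_chain(s)
    for (k in seq_along(chain)) {
      r <- cv_rmse(chain[seq_len(k)])
      if (r < best$rmse - 1e-15) best <- list(rmse = r, start = s, k = k,
                                              cols = chain[seq_len(k)])
    }
  }
  best
}

# ---- shared default pipeline bundle (computed once per test run) --------
.bundle_env <- new.env(parent = emptyenv())
default_bundle <- function() {
  if (is.null(.bundle_env$bundle)) {
    .bundle_env$bundle <- run_pipeline(default_config(0))
  }
  .bundle_env$bundle
}

# small random integer window helper
random_window <- function(n = 5, G = 8) {
  matrix(sample.int(G, n * n, replace = TRUE) - 1L, n, n)
}
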