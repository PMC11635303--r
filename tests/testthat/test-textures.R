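test_that("first principal component matches eigenstructure", {
  wl <- c(500, 600)
  # 3-pixel, 2-band toy: closed-form 2x2 covariance eigendecomposition
  vals <- array(0, dim = c(1, 3, 2))
  vals[1, , 1] <- c(0.1, 0.2, 0.6)
  vals[1, , 2] <- c(0.3, 0.1, 0.5)
  cube <- reflectance_cube(vals, wl)
  pc <- pca_first_component(cube)
  X <- cbind(vals[1, , 1], vals[1, , 2])
  S <- stats::cov(X)
  eig <- eigen(S, symmetric = TRUE)
  expect_equal(pc$explained_variance_ratio, eig$values[1] / sum(eig$values),
               tolerance = 1e-9)
  v <- eig$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  expect_equal(as.vector(pc$values), as.vector(scale(X, scale = FALSE) %*% v),
               tolerance = 1e-9)

  # rank-1 cube: single nonzero eigenvalue
  base <- c(0.2, 0.7)
  vals1 <- array(0, dim = c(2, 3, 2))
  scl <- matrix(runif(6, 0.5, 1.5), 2, 3)
  for (b in 1:2) vals1[, , b] <- scl * base[b]
  pc1 <- pca_first_component(reflectance_cube(vals1, wl))
  expect_equal(pc1$explained_variance_ratio, 1.0, tolerance = 1e-9)

  # degenerate (constant) cube errors
  expect_error(pca_first_component(reflectance_cube(array(0.5, c(2, 2, 2)), wl)),
               "degenerate")
  # masked pixels are excluded from the decomposition
  mask <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2, 3)
  pcm <- pca_first_component(reflectance_cube(vals1, wl, mask = mask))
  expect_true(all(is.na(pcm$values[!mask])))
})

test_that("quantization stretches the 2-98 percentile range onto 0..G-1", {
  expect_true(all(quantize(matrix(5, 4, 4), 32) == 0L))
  ramp <- matrix(seq(0, 1, length.out = 400), 20, 20)
  q4 <- quantize(ramp, 4)
  expect_setequal(sort(unique(as.vector(q4))), 0:3)
  counts <- table(q4)
  expect_true(max(counts) / min(counts) < 1.3)   # near-equal level bands
  set.seed(5)
  qr <- quantize(matrix(rnorm(100), 10, 10), 8)
  expect_true(all(qr >= 0 & qr <= 7))
})

test_that("co-occurrence matrices count 45-degree neighbor pairs", {
  # constant window: all mass at (0, 0)
  m <- glcm_window(matrix(0L, 5, 5), G = 4)
  expect_equal(m$p[1, 1], 1)
  expect_equal(sum(m$p), 1)
  expect_equal(m$n_pairs, 16L)   # 4 x 4 in-window pairs at offset (-1, +1)

  # two-level checkerboard: equal neighbors along the 45-degree diagonal
  cb <- outer(1:5, 1:5, function(r, c) (r + c) %% 2L)
  mcb <- glcm_window(cb, G = 2)
  expect_equal(mcb$p[1, 2] + mcb$p[2, 1], 0)
  expect_equal(sum(diag(mcb$p)), 1)

  set.seed(9)
  for (rep_i in 1:20) {
    q <- random_window(5, 6)
    m <- glcm_window(q, G = 6)
    expect_equal(sum(m$p), 1, tolerance = 1e-9)
    expect_equal(m$p, t(m$p))                       # symmetrized
    expect_equal(m$p, oracle_glcm(q, 6), tolerance = 1e-12)
  }
  qna <- matrix(0L, 5, 5); qna[3, 3] <- NA
  expect_error(glcm_window(qna, 4), "masked")
})

test_that("simple Haralick features match closed forms and the oracle", {
  # concentrated distribution
  m1 <- glcm_window(matrix(2L, 5, 5), G = 4)
  h1 <- haralick_simple(m1)
  expect_equal(unname(h1[c("Energy", "Entropy", "Inertia",
                           "InverseDifferenceMoment")]), c(1, 0, 0, 1))
  expect_true(attr(h1, "degenerate"))
  expect_equal(unname(h1[c("Correlation", "HaralickCorrelation")]), c(0, 0))
  # uniform 2x2 GLCM
  m2 <- structure(list(p = matrix(0.25, 2, 2), levels = 2L,
                       offset = c(-1L, 1L), symmetric = TRUE), class = "glcm")
  h2 <- haralick_simple(m2)
  expect_equal(unname(h2["Energy"]), 0.25)
  expect_equal(unname(h2["Entropy"]), log(4))
})

test_that("advanced Haralick features match closed forms", {
  m1 <- glcm_window(matrix(3L, 5, 5), G = 8)
  a1 <- haralick_advanced(m1)
  expect_equal(unname(a1[c("Mean", "Variance", "Dissimilarity")]), c(3, 0, 0))
  # symmetric GLCM: Mean equals both marginal means
  set.seed(13)
  q <- random_window(5, 4)
  m <- glcm_window(q, 4)
  px <- rowSums(m$p)
  expect_equal(unname(haralick_advanced(m)["Mean"]), sum((0:3) * px),
               tolerance = 1e-12)
})

test_that("all 18 GLCM features agree with the brute-force oracle", {
  set.seed(17)
  for (rep_i in 1:40) {
    G <- sample(3:8, 1)
    q <- random_window(5, G)
    m <- glcm_window(q, G)
    got <- c(haralick_simple(m), haralick_advanced(m))
    want <- oracle_haralick(m$p)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-9)
  }
})

test_that("run-length matrices trace maximal 45-degree runs", {
  rl <- glrlm_window(matrix(1L, 5, 5), G = 4)
  expect_equal(rl$Nr, 9)                     # diagonals 1,2,3,4,5,4,3,2,1
  expect_equal(unname(runlength_features(rl)["RunPercentage"]), 9 / 25)
  expect_equal(rl$r[2, ], c(2, 2, 2, 2, 1))  # one run per diagonal length

  # row-parity stripes alternate along every 45-degree diagonal:
  # all 25 runs have length 1
  alt <- outer(1:5, 1:5, function(r, c) r %% 2L)
  rl2 <- glrlm_window(alt, G = 2)
  expect_equal(rl2$Nr, 25)
  f2 <- runlength_features(rl2)
  expect_equal(unname(f2["ShortRunEmphasis"]), 1)
  expect_equal(unname(f2["LongRunEmphasis"]), 1)
  # pixel conservation for random windows
  set.seed(21)
  for (rep_i in 1:25) {
    q <- random_window(5, 3)
    rl <- glrlm_window(q, 3)
    expect_equal(sum(sweep(rl$r, 2, seq_len(ncol(rl$r)), "*")), 25)
    expect_equal(rl$r, oracle_glrlm(q, 3))
  }
})

test_that("run-length features agree with the brute-force oracle", {
  # constant window: a single gray level, GLN = Nr
  rlc <- glrlm_window(matrix(2L, 5, 5), G = 4)
  expect_equal(unname(runlength_features(rlc)["GreyLevelNonuniformity"]), rlc$Nr)
  set.seed(23)
  for (rep_i in 1:40) {
    G <- sample(2:6, 1)
    q <- random_window(5, G)
    rl <- glrlm_window(q, G)
    got <- runlength_features(rl)
    want <- oracle_runlength_features(rl$r, 25)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-9)
  }
})

test_that("sliding-window maps equal the per-window R reference", {
  set.seed(29)
  img <- matrix(sample.int(6, 12 * 12, replace = TRUE) - 1L, 12, 12)
  maps <- texture_maps(img, G = 6, window = 5)
  for (r in c(3, 6, 10)) {
    for (cc in c(3, 7, 10)) {
      win <- img[(r - 2):(r + 2), (cc - 2):(cc + 2)]
      want <- window_texture_features(win, G = 6)
      expect_equal(unname(maps[r, cc, ]), unname(want[texture_feature_names()]),
                   tolerance = 1e-9)
    }
  }
  # edges and masked windows are NA
  expect_true(all(is.na(maps[1:2, , ])))
  img_na <- img; img_na[6, 6] <- NA
  maps_na <- texture_maps(img_na, G = 6, window = 5)
  expect_true(all(is.na(maps_na[5:8, 5:8, 1])))
  expect_equal(maps_na[3, 3, ], maps[3, 3, ])
})

test_that("texture feature table aggregates window maps per plot", {
  # toy scene: one plot polygon over a 12x12 image, pixel size 1
  set.seed(31)
  img <- matrix(rnorm(144), 12, 12)
  pc1 <- structure(list(values = img, explained_variance_ratio = 1,
                        mask = matrix(TRUE, 12, 12)), class = "pc_image")
  lay <- data.frame(plot_id = 1L)
  lay$polygon <- list(rbind(c(2, 2), c(10, 2), c(10, 10), c(2, 10), c(2, 2)))
  tab <- texture_feature_table(pc1, lay, G = 8, window = 5, pixel_size = 1)
  expect_equal(dim(tab), c(1L, 2L + 28L))
  # explicit window list oracle: mean over in-polygon pixel centers
  q <- quantize(img, 8)
  maps <- texture_maps(q, 8, 5)
  centers_x <- rep((1:12) - 0.5, each = 12)
  centers_y <- rep((1:12) - 0.5, times = 12)
  inside <- points_in_ring(centers_x, centers_y, lay$polygon[[1]])
  flat <- matrix(maps, 144, 28)
  keep <- inside & stats::complete.cases(flat)
  expect_equal(unname(as.numeric(tab[1, -(1:2)])), unname(colMeans(flat[keep, ])),
               tolerance = 1e-12)

  # constant image: Energy 1, Entropy 0 for the plot
  pc_const <- structure(list(values = matrix(0, 12, 12),
                             explained_variance_ratio = 1,
                             mask = matrix(TRUE, 12, 12)), class = "pc_image")
  tc <- texture_feature_table(pc_const, lay, G = 8, window = 5, pixel_size = 1)
  expect_equal(tc$TEX_Energy, 1)
  expect_equal(tc$TEX_Entropy, 0)
})

test_that("window texture tracks the generator's roughness parameter", {
  # clean signal path: nuisance fields off isolates roughness -> texture
  lay <- make_layout(0)
  truth <- simulate_lai_all_stages(lay, seed = 0)
  cube <- simulate_cube(lay, truth, "BBCH41", seed = 0, noise_sd = 0,
                        illum_sd = 0, soil_moist_sd = 0, micro_amp = 0)
  pc <- pca_first_component(cube)
  tab <- texture_feature_table(pc, lay, stage = "BBCH41")
  rough <- attr(cube, "plot_roughness")
  rho_inertia <- stats::cor(rough[1:20], tab$TEX_Inertia[1:20], method = "spearman")
  rho_entropy <- stats::cor(rough[1:20], tab$TEX_Entropy[1:20], method = "spearman")
  expect_gte(abs(rho_inertia), 0.8)
  expect_gte(abs(rho_entropy), 0.8)
})
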