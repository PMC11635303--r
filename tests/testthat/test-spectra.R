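toy_cube <- function(values, wavelengths, mask = NULL, pixel_size = 1) {
  reflectance_cube(values, wavelengths, mask = mask, pixel_size = pixel_size)
}

test_that("plot-mean spectra are unweighted means over in-polygon valid pixels", {
  wl <- seq(450, by = 4, length.out = 5)
  vals <- array(0.3, dim = c(4, 4, 5))
  cube <- toy_cube(vals, wl)
  lay <- data.frame(plot_id = 1L)
  lay$polygon <- list(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4), c(0, 0)))
  sp <- plot_mean_spectrum(cube, lay)
  expect_equal(as.vector(sp$reflectance), rep(0.3, 5))

  # two-pixel plot: mean of the two spectra
  vals2 <- array(runif(4 * 4 * 5), dim = c(4, 4, 5))
  cube2 <- toy_cube(vals2, wl)
  lay2 <- data.frame(plot_id = 1L)
  lay2$polygon <- list(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1), c(0, 0)))
  sp2 <- plot_mean_spectrum(cube2, lay2)
  expect_equal(as.vector(sp2$reflectance),
               as.vector((vals2[1, 1, ] + vals2[1, 2, ]) / 2))

  # masked pixels are excluded; fully masked plot errors
  mask <- matrix(TRUE, 4, 4); mask[1, 2] <- FALSE
  sp3 <- plot_mean_spectrum(toy_cube(vals2, wl, mask), lay2)
  expect_equal(as.vector(sp3$reflectance), as.vector(vals2[1, 1, ]))
  mask[1, 1] <- FALSE
  expect_error(plot_mean_spectrum(toy_cube(vals2, wl, mask), lay2),
               "no valid pixels")

  # full design: 48 records
  lay48 <- make_layout(0)
  truth <- simulate_lai_all_stages(lay48, seed = 0)
  cube48 <- simulate_cube(lay48, truth, "BBCH41", seed = 0)
  expect_equal(nrow(plot_mean_spectrum(cube48, lay48)$reflectance), 48L)
})

test_that("differential transform matches its printed finite-difference form", {
  expect_equal(fdsr(rep(0.4, 10)), rep(0, 10))
  # linear ramp with slope b per nm: (R(i-1) - R(i+1)) / 4 = -2b
  b <- 0.002
  wl <- seq(450, by = 4, length.out = 20)
  ramp <- 0.1 + b * (wl - 450)
  out <- fdsr(ramp, delta_lambda = 4)
  expect_equal(out, rep(-2 * b, 20), tolerance = 1e-12)
  # conventional central-difference flag
  out_c <- fdsr(ramp, delta_lambda = 4, convention = "central")
  expect_equal(out_c, rep(b, 20), tolerance = 1e-12)
  # element-wise loop oracle on a random 10-channel vector
  set.seed(42)
  x <- runif(10)
  manual <- numeric(10)
  for (i in 2:9) manual[i] <- (x[i - 1] - x[i + 1]) / 4
  manual[1] <- manual[2]; manual[10] <- manual[9]
  expect_equal(fdsr(x, 4), manual, tolerance = 1e-12)
  expect_error(fdsr(c(1, 2)), "at least 3")
})

test_that("differential transform is linear at interior channels", {
  set.seed(7)
  for (rep_i in 1:20) {
    x <- runif(30); y <- runif(30); a <- rnorm(1)
    lhs <- fdsr(a * x + y, 4)
    rhs <- a * fdsr(x, 4) + fdsr(y, 4)
    expect_equal(lhs[2:29], rhs[2:29], tolerance = 1e-10)
  }
})

test_that("vegetation-index registry reproduces the published formulas", {
  reg <- vi_registry()
  expect_length(reg, 30L)
  expect_identical(names(reg)[c(1, 12, 30)], c("DVI", "NDVI", "WDRVI"))
  wl <- seq(450, by = 4, length.out = 125)
  # spot values by direct substitution
  refl <- rep(0.3, 125)
  refl[nearest_channel(800, wl)] <- 0.5
  refl[nearest_channel(680, wl)] <- 0.1
  expect_equal(compute_vi(refl, wl, "NDVI"), (0.5 - 0.1) / (0.5 + 0.1),
               tolerance = 1e-12)
  refl[nearest_channel(800, wl)] <- 0.1
  expect_equal(compute_vi(refl, wl, "NDVI"), 0, tolerance = 1e-12)
  expect_error(compute_vi(refl, wl, "NOPE"), "unknown vegetation index")
  # all 30 against the hand-coded oracle sheet, several random spectra
  set.seed(11)
  for (rep_i in 1:25) {
    r <- runif(125, 0.02, 0.9)
    sheet <- oracle_vi_sheet(r, wl)
    for (nm in names(reg)) {
      expect_equal(compute_vi(r, wl, nm), sheet[[nm]], tolerance = 1e-9,
                   label = nm)
    }
  }
})

test_that("normalized-difference indices stay within [-1, 1]", {
  wl <- seq(450, by = 4, length.out = 125)
  set.seed(3)
  for (rep_i in 1:50) {
    r <- runif(125, 1e-4, 1)
    for (nm in c("NDVI", "GNDVI", "NDRE", "NPCI", "NRI")) {
      v <- compute_vi(r, wl, nm)
      expect_true(v >= -1 && v <= 1, label = nm)
    }
  }
})

test_that("band lookup resolves ties toward the lower wavelength", {
  wl <- seq(450, by = 4, length.out = 125)
  # 800 nm is equidistant from 798 and 802
  expect_equal(wl[nearest_channel(800, wl)], 798)
  expect_equal(wl[nearest_channel(886, wl)], 886)
  expect_equal(wl[nearest_channel(449, wl)], 450)
})

test_that("spectral feature table has the published family structure", {
  lay <- make_layout(0)
  truth <- simulate_lai_all_stages(lay, seed = 0)
  cube <- simulate_cube(lay, truth, "BBCH41", seed = 0)
  sp <- plot_mean_spectrum(cube, lay)
  tab <- build_spectral_features(sp)
  fam <- feature_families(tab)
  expect_equal(as.integer(table(fam)[c("OSR", "FDSR", "VI")]), c(125L, 125L, 30L))
  expect_equal(ncol(tab), 2 + 280)
  expect_false(anyNA(tab))
  expect_equal(anyDuplicated(colnames(tab)), 0L)
  # constant spectra give all-zero differential columns
  spc <- sp
  spc$reflectance <- matrix(0.4, nrow(sp$reflectance), 125)
  tabc <- build_spectral_features(spc)
  expect_true(all(abs(as.matrix(tabc[, grep("^FDSR_", colnames(tabc))])) < 1e-12))
})
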