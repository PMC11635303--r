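make_world <- function(seed = 0) {
  lay <- make_layout(seed)
  truth <- simulate_lai_all_stages(lay, seed = seed)
  list(lay = lay, truth = truth)
}

test_that("simulated cube honors the sensor's band layout and value range", {
  w <- make_world()
  cube <- simulate_cube(w$lay, w$truth, "BBCH41", seed = 0)
  expect_equal(dim(cube$values)[3], 125L)
  expect_equal(cube$wavelengths, seq(450, by = 4, length.out = 125))
  expect_lt(diff(range(diff(cube$wavelengths))), 1e-9)
  expect_true(all(cube$values >= 0 & cube$values <= 1.2))
  expect_true(all(cube$wavelengths >= 450 & cube$wavelengths <= 950))
  # bit-identical regeneration under the same seed
  cube2 <- simulate_cube(w$lay, w$truth, "BBCH41", seed = 0)
  expect_identical(cube$values, cube2$values)
  # missing truth record is an error
  expect_error(simulate_cube(w$lay, w$truth[-1, ], "BBCH41", seed = 0),
               "no ground-truth record")
})

test_that("saturated cover degenerates to the pure leaf spectrum", {
  w <- make_world()
  # force full cover everywhere in plots: huge extinction, no variability
  cube <- simulate_cube(w$lay, w$truth, "BBCH41", seed = 0, k_ext = 1000,
                        k_ext_jitter_sd = 0, noise_sd = 0, roughness_base = 0,
                        rough_jitter_sd = 0, stripe_amp = 0, micro_amp = 0,
                        illum_sd = 0, soil_moist_sd = 0)
  sp <- plot_mean_spectrum(cube, w$lay)
  # every plot shows the identical (leaf) spectrum ...
  expect_lt(max(apply(sp$reflectance, 2, function(x) diff(range(x)))), 1e-12)
  # ... with the vegetation shape: NIR plateau far above the red trough
  r670 <- sp$reflectance[1, nearest_channel(670, sp$wavelengths)]
  r850 <- sp$reflectance[1, nearest_channel(850, sp$wavelengths)]
  expect_gt(r850, 5 * r670)
})

test_that("plot-mean NDVI increases with LAI in the noise-free mixture", {
  w <- make_world()
  truth <- w$truth[w$truth$stage == "BBCH41", ]
  truth$lai <- rep_len(c(0.5, 1.5, 3.0), 48)   # controlled LAI levels
  cube <- simulate_cube(w$lay, truth, "BBCH41", seed = 0,
                        k_ext_jitter_sd = 0, noise_sd = 0, roughness_base = 0,
                        rough_jitter_sd = 0, micro_amp = 0, illum_sd = 0,
                        soil_moist_sd = 0)
  sp <- plot_mean_spectrum(cube, w$lay)
  ndvi <- compute_vi(sp$reflectance, sp$wavelengths, "NDVI")
  m <- tapply(ndvi, truth$lai, mean)
  expect_true(m[["0.5"]] < m[["1.5"]] && m[["1.5"]] < m[["3"]])
  # and every plot triple is strictly ordered
  expect_true(all(ndvi[truth$lai == 0.5] < min(ndvi[truth$lai == 3])))
})

test_that("NIR reflectance correlates positively with LAI across the design", {
  b <- default_bundle()
  nir <- b$features$OSR_886
  expect_gt(cor(nir, b$samples$lai), 0)
})

test_that("ENVI BSQ round trip preserves the cube", {
  w <- make_world()
  cube <- simulate_cube(w$lay, w$truth, "BBCH44", seed = 3)
  path <- file.path(tempdir(), "cube_rt")
  write_cube_envi(cube, path)
  back <- read_cube_envi(path)
  expect_equal(back$wavelengths, cube$wavelengths)
  expect_equal(back$pixel_size, cube$pixel_size)
  expect_equal(back$values, cube$values, tolerance = 1e-6)  # float32 storage
  unlink(paste0(path, c(".bsq", ".hdr")))
})
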