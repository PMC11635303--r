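#' Default pipeline configuration
#'
#' One list, fully serializable to JSON, from which a run is reproducible
#' given the master seed alone.
#'
#' @param seed master seed.
#' @param ... overrides of the defaults.
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 0L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    stages = c("BBCH41", "BBCH44", "BBCH47"),
    wavelength_origin = 450, wavelength_step = 4, n_channels = 125L,
    pixel_size = 0.25,
    lai_noise_sd = 0.35,
    k_ext = 0.5, k_ext_jitter_sd = 0.1, noise_sd = 0.01,
    roughness_base = 0.12, rough_jitter_sd = 0.08, stripe_amp = 0.25,
    illum_sd = 0.08, illum_scale_px = 3, micro_amp = 0.05,
    soil_moist_sd = 0.12, soil_moist_scale_px = 12,
    glcm_levels = 32L, glcm_window = 5L, glcm_offset = c(-1L, 1L),
    fdsr_convention = "paper",
    spa_kmax = NULL, spa_folds = 5L,
    methods = c("PLSR", "RFR", "GPR"),
    families = c("OSR", "FDSR", "VI", "TEX", "ALL"),
    write_maps = FALSE,
    out_dir = NULL
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as JSON
#' @param config a `run_config`.
#' @param path file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$glcm_offset)) cfg$glcm_offset <- as.integer(cfg$glcm_offset)
  class(cfg) <- "run_config"
  cfg
}

#' Extract all features of one stage cube
#'
#' Plot-mean spectra (OSR/FDSR/VI block) plus PC1 texture features, joined on
#' plot and stage.
#'
#' @param cube a `reflectance_cube` for one stage.
#' @param layout a `plot_layout`.
#' @param config a `run_config`.
#' @return list with `features` (one-stage `feature_table`, 48 x 308 on
#'   defaults), `pc1`, `spectra`.
#' @export
extract_stage_features <- function(cube, layout, config = default_config()) {
  spectra <- plot_mean_spectrum(cube, layout)
  spec_tab <- build_spectral_features(spectra,
                                      fdsr_convention = config$fdsr_convention)
  pc1 <- pca_first_component(cube)
  tex_tab <- texture_feature_table(pc1, layout, G = config$glcm_levels,
                                   window = config$glcm_window,
                                   offset = config$glcm_offset,
                                   pixel_size = cube$pixel_size,
                                   stage = cube$stage)
  list(features = bind_feature_tables(spec_tab, tex_tab), pc1 = pc1,
       spectra = spectra)
}

#' Run the full pipeline: simulate, extract, select, train, evaluate, map
#'
#' Orchestrates the whole analysis from one configuration: trial layout and
#' ground truth, one cube per growth stage, the 308-column combined feature
#' table, correlation screening, SPA selection and the 5-family x 3-method
#' model grid, and (optionally) per-stage LAI maps from the best validation
#' model. When `config$out_dir` is set, intermediate artifacts (layout
#' GeoJSON, truth CSV, cubes as ENVI rasters, feature CSV, SPA JSONs, report
#' CSVs) are written there so any stage can be re-run from disk.
#'
#' @param config a `run_config` from [default_config()].
#' @return a bundle list: `layout`, `truth`, `cubes`, `features`, `samples`,
#'   `screen`, `experiment`, `maps` (if requested), `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  seed <- config$seed
  wl <- default_wavelengths(config$wavelength_origin, config$wavelength_step,
                            config$n_channels)
  layout <- make_layout(seed, pixel_size = config$pixel_size)
  truth <- do.call(rbind, lapply(config$stages, simulate_lai, layout = layout,
                                 seed = seed, noise_sd = config$lai_noise_sd))
  cubes <- lapply(config$stages, function(st)
    simulate_cube(layout, truth, st, seed = seed,
                  k_ext = config$k_ext, k_ext_jitter_sd = config$k_ext_jitter_sd,
                  noise_sd = config$noise_sd,
                  roughness_base = config$roughness_base,
                  rough_jitter_sd = config$rough_jitter_sd,
                  stripe_amp = config$stripe_amp,
                  illum_sd = config$illum_sd,
                  illum_scale_px = config$illum_scale_px,
                  micro_amp = config$micro_amp,
                  soil_moist_sd = config$soil_moist_sd,
                  soil_moist_scale_px = config$soil_moist_scale_px,
                  wavelengths = wl))
  names(cubes) <- config$stages
  extracted <- lapply(cubes, extract_stage_features, layout = layout,
                      config = config)
  features <- do.call(rbind, lapply(extracted, `[[`, "features"))
  attr(features, "family") <- attr(extracted[[1]]$features, "family")
  class(features) <- c("feature_table", "data.frame")
  rownames(features) <- NULL
  # align samples with feature rows on (plot_id, stage)
  idx <- match(paste(features$plot_id, features$stage),
               paste(truth$plot_id, truth$stage))
  samples <- truth[idx, ]
  screen <- correlation_screen(features, samples$lai)
  experiment <- run_experiment(features, samples,
                               methods = config$methods,
                               families = config$families,
                               spa_kmax = config$spa_kmax,
                               spa_folds = config$spa_folds, seed = seed)
  maps <- NULL
  if (isTRUE(config$write_maps) || !is.null(config$out_dir)) {
    best_fit <- experiment$models[[experiment$best$family]][[experiment$best$method]]
    best_cols <- experiment$selected[[experiment$best$family]]$chosen_columns
    maps <- lapply(cubes, function(cb)
      write_lai_map(best_fit, best_cols, cb, layout, config = config))
  }
  bundle <- list(layout = layout, truth = truth, cubes = cubes,
                 features = features, samples = samples, screen = screen,
                 experiment = experiment, maps = maps, config = config)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(bundle$config, file.path(out_dir, "config.json"))
  write_layout_geojson(bundle$layout, file.path(out_dir, "layout.geojson"))
  utils::write.csv(bundle$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  for (st in names(bundle$cubes)) {
    write_cube_envi(bundle$cubes[[st]], file.path(out_dir, paste0("cube_", st)))
  }
  write_feature_table(bundle$features, file.path(out_dir, "features.csv"))
  utils::write.csv(bundle$screen, file.path(out_dir, "correlation_screen.csv"),
                   row.names = FALSE)
  for (fam in names(bundle$experiment$selected)) {
    write_spa_result(bundle$experiment$selected[[fam]],
                     file.path(out_dir, paste0("spa_", fam, ".json")))
  }
  utils::write.csv(bundle$experiment$reports,
                   file.path(out_dir, "model_reports.csv"), row.names = FALSE)
  utils::write.csv(bundle$experiment$per_stage,
                   file.path(out_dir, "per_stage_validation.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$maps)) {
    for (st in names(bundle$maps)) {
      map <- bundle$maps[[st]]
      cube1 <- reflectance_cube(array(ifelse(is.na(map), -9999, map),
                                      dim = c(dim(map), 1L)),
                                wavelengths = 0,
                                pixel_size = bundle$config$pixel_size)
      write_cube_envi(cube1, file.path(out_dir, paste0("lai_map_", st)))
    }
  }
  invisible(out_dir)
}

# Per-pixel values of the named feature columns over a cube. Returns a
# pixels x features matrix (pixel-major, column order) with NA where a
# feature is not computable (masked pixel or texture edge).
pixel_feature_matrix <- function(cube, columns, config = default_config()) {
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  wl <- cube$wavelengths
  dl <- wl[2] - wl[1]
  out <- matrix(NA_real_, nrow(flat), length(columns))
  colnames(out) <- columns
  tex_cols <- grep("^TEX_", columns, value = TRUE)
  tex_flat <- NULL
  if (length(tex_cols)) {
    pc1 <- pca_first_component(cube)
    q <- quantize(pc1$values, config$glcm_levels, mask = pc1$mask)
    maps <- texture_maps(q, config$glcm_levels, config$glcm_window,
                         config$glcm_offset)
    tex_flat <- matrix(maps, d[1] * d[2], dim(maps)[3])
    colnames(tex_flat) <- paste0("TEX_", texture_feature_names())
  }
  for (col in columns) {
    if (startsWith(col, "OSR_")) {
      ch <- nearest_channel(as.numeric(sub("OSR_", "", col)), wl)
      out[, col] <- flat[, ch]
    } else if (startsWith(col, "FDSR_")) {
      ch <- nearest_channel(as.numeric(sub("FDSR_", "", col)), wl)
      i <- min(max(ch, 2L), d[3] - 1L)   # endpoint channels replicate inward
      if (config$fdsr_convention == "central") {
        out[, col] <- (flat[, i + 1L] - flat[, i - 1L]) / (2 * dl)
      } else {
        out[, col] <- (flat[, i - 1L] - flat[, i + 1L]) / dl
      }
    } else if (startsWith(col, "TEX_")) {
      out[, col] <- tex_flat[, col]
    } else {
      out[, col] <- compute_vi(flat, wl, col)
    }
  }
  out[!as.vector(cube$mask), ] <- NA_real_
  out
}

#' Predict a per-pixel LAI map
#'
#' Applies a plot-level-trained model pixel-wise: spectral features come from
#' the pixel spectrum, texture features from the window centered on the
#' pixel. Pixels outside every plot polygon, masked pixels, and pixels whose
#' features are not computable (texture edge windows) are NA.
#'
#' @param model a fitted model (`plsr_fit`, `rfr_fit`, `gpr_fit`).
#' @param columns feature column names the model was trained on.
#' @param cube a `reflectance_cube`.
#' @param layout a `plot_layout`; set `NULL` to predict all valid pixels.
#' @param config a `run_config` (texture/FDSR conventions).
#' @param clip_range optional `c(lo, hi)` to clip predictions to a physically
#'   plausible LAI range (single pixels can sit far outside the plot-mean
#'   feature domain the model was trained on); `NULL` (default) leaves
#'   predictions unclipped.
#' @return H x W numeric matrix of predicted LAI, NA outside plots.
#' @export
write_lai_map <- function(model, columns, cube, layout,
                          config = default_config(), clip_range = NULL) {
  d <- dim(cube$values)
  feats <- pixel_feature_matrix(cube, columns, config)
  keep <- stats::complete.cases(feats)
  if (!is.null(layout)) {
    ctr <- pixel_centers(cube)
    px_grid <- rep(ctr$x, each = d[1])
    py_grid <- rep(ctr$y, times = d[2])
    in_plot <- rep(FALSE, length(px_grid))
    for (i in seq_len(nrow(layout))) {
      in_plot <- in_plot | points_in_ring(px_grid, py_grid, layout$polygon[[i]])
    }
    keep <- keep & in_plot
  }
  map <- matrix(NA_real_, d[1], d[2])
  if (any(keep)) {
    map[keep] <- predict(model, feats[keep, , drop = FALSE])
    if (!is.null(clip_range)) {
      map[keep] <- pmin(pmax(map[keep], clip_range[1]), clip_range[2])
    }
  }
  map
}
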