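#' Default wavelength grid
#'
#' 125 channels at 4 nm sampling starting at 450 nm (450-946 nm). The sensor
#' is nominally specified as "450-950 nm, 125 channels, 4 nm" which is
#' internally inconsistent by one channel; the channel count is honored and
#' the grid origin is configurable.
#'
#' @param origin_nm first channel wavelength (default 450).
#' @param step_nm sampling interval (default 4).
#' @param n_channels number of channels (default 125).
#' @return numeric vector of wavelengths in nm.
#' @export
default_wavelengths <- function(origin_nm = 450, step_nm = 4, n_channels = 125L) {
  origin_nm + step_nm * (seq_len(n_channels) - 1)
}

#' Construct a reflectance cube
#'
#' @param values H x W x B array of reflectance in [0, 1.2].
#' @param wavelengths strictly increasing, uniformly spaced (nm), length B.
#' @param mask H x W logical matrix of valid pixels (default all TRUE).
#' @param pixel_size ground sampling distance in metres.
#' @param stage optional growth-stage label carried as metadata.
#' @return a `reflectance_cube` (list with `values`, `wavelengths`, `mask`,
#'   `pixel_size`, `stage`).
#' @export
reflectance_cube <- function(values, wavelengths, mask = NULL,
                             pixel_size = 0.25, stage = NULL) {
  stopifnot(length(dim(values)) == 3)
  B <- dim(values)[3]
  if (length(wavelengths) != B) stop("wavelengths must match band count", call. = FALSE)
  if (B > 1) {
    steps <- diff(wavelengths)
    if (any(steps <= 0) || diff(range(steps)) > 1e-9) {
      stop("wavelengths must be strictly increasing with a uniform step",
           call. = FALSE)
    }
  }
  if (is.null(mask)) mask <- matrix(TRUE, dim(values)[1], dim(values)[2])
  stopifnot(identical(dim(mask), dim(values)[1:2]))
  structure(list(values = values, wavelengths = wavelengths, mask = mask,
                 pixel_size = pixel_size, stage = stage),
            class = "reflectance_cube")
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("reflectance_cube: %d x %d pixels, %d bands (%.0f-%.0f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$stage %||% "no stage"))
  invisible(x)
}

#' Pixel-center scene coordinates of a cube
#' @param cube a `reflectance_cube`.
#' @return list with vectors `x` (per column) and `y` (per row), metres.
#' @export
pixel_centers <- function(cube) {
  d <- dim(cube$values)
  list(x = (seq_len(d[2]) - 0.5) * cube$pixel_size,
       y = (seq_len(d[1]) - 0.5) * cube$pixel_size)
}

# Fresh green-leaf reflectance archetype: blue/red chlorophyll absorption,
# green peak near 550 nm, logistic red-edge ramp onto a NIR plateau. Stage
# parameters shift the red trough and the NIR plateau (mild senescence by
# starch accumulation).
leaf_spectrum <- function(wavelengths, stage = "BBCH41") {
  p <- switch(stage,
    BBCH41 = list(red = 0.040, green = 0.085, nir = 0.52, edge_mid = 718),
    BBCH44 = list(red = 0.045, green = 0.080, nir = 0.50, edge_mid = 720),
    BBCH47 = list(red = 0.055, green = 0.075, nir = 0.48, edge_mid = 722),
    stop(sprintf("unknown stage '%s'", stage), call. = FALSE))
  base <- p$red +
    p$green * exp(-(wavelengths - 552)^2 / (2 * 28^2)) +
    (p$nir - p$red) / (1 + exp(-(wavelengths - p$edge_mid) / 9))
  # weak water-related dip near 940 nm
  base - 0.02 * exp(-(wavelengths - 940)^2 / (2 * 15^2))
}

# Bare-soil archetype: featureless, brightening with wavelength. The soil
# dries (brightens) between acquisition dates, so each stage sees a different
# background level — a between-flight nuisance that ratio indices largely
# cancel but raw reflectance and scene-relative texture levels do not.
soil_spectrum <- function(wavelengths, stage = "BBCH41") {
  bright <- switch(stage, BBCH41 = 0.90, BBCH44 = 1.0, BBCH47 = 1.10, 1.0)
  bright * (0.08 + 0.00034 * (wavelengths - 450))
}

# Correlated random field: white noise smoothed with a separable Gaussian
# kernel, rescaled to unit variance.
gaussian_random_field <- function(nrow, ncol, sigma = 1.5) {
  z <- matrix(rnorm(nrow * ncol), nrow, ncol)
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_smooth <- function(m) {
    # reflect-pad rows then convolve each column, vectorized via apply
    mp <- m[c(rev(seq_len(r)), seq_len(nrow(m)), nrow(m) + 1 - seq_len(r)), , drop = FALSE]
    sm <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
    sm[(r + 1):(r + nrow(m)), , drop = FALSE]
  }
  z <- pad_smooth(z)
  z <- t(pad_smooth(t(z)))
  z <- z - mean(z)
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

#' Simulate a hyperspectral reflectance cube for one growth stage
#'
#' Every pixel is a vegetation/soil linear mixture
#' `R(lambda) = f * R_leaf(lambda) + (1 - f) * R_soil(lambda)` where `f` is
#' the pixel's vegetation cover fraction. The plot-mean cover follows a
#' Beer-Lambert law in the plot LAI, `f_plot = 1 - exp(-k_ext * LAI)`; within
#' the plot, cover varies as planting-row stripes (fixed 4-pixel pitch, with
#' amplitude proportional to `f (1 - f)` so rows vanish on bare soil and at
#' canopy closure) plus a correlated
#' Gaussian random field whose amplitude (spatial roughness) decreases as the
#' plot LAI increases: sparse canopies are patchy, closed canopies smooth.
#' That law is what gives image texture its predictive signal. The plot-level
#' extinction coefficient is jittered (lognormally around `k_ext`), so
#' plot-mean reflectance is an informative but imperfect proxy of LAI. Pixels
#' outside any plot are bare soil. A smooth multiplicative illumination gain
#' and a soil-moisture brightness field supply LAI-independent nuisance
#' structure; additive Gaussian sensor noise `noise_sd` is applied per band
#' and the result clipped to [0, 1.2].
#'
#' @param layout a `plot_layout`.
#' @param truth ground-truth data.frame covering every plot at `stage`.
#' @param stage growth-stage label.
#' @param seed integer master seed.
#' @param k_ext nominal canopy extinction coefficient (default 0.5).
#' @param k_ext_jitter_sd lognormal sd (log scale) of the per-plot extinction
#'   jitter (default 0.1); 0 disables it. Canopy architecture varies between
#'   plots, so reflectance is an informative but imperfect proxy of LAI.
#' @param noise_sd additive sensor noise, reflectance units (default 0.01).
#' @param roughness_base amplitude of the within-plot cover random field
#'   (cover-fraction units) at LAI 0 (default 0.12); per-plot amplitude is
#'   `roughness_base / (1 + lai)` times lognormal plot jitter: patchiness
#'   declines toward canopy closure.
#' @param rough_jitter_sd log-sd of the per-plot roughness jitter (default
#'   0.08): canopy patchiness tracks LAI only loosely, so texture is an
#'   informative but noisy LAI proxy.
#' @param stripe_amp planting-row stripe amplitude (default 0.25).
#' @param illum_sd log-sd of a smooth multiplicative illumination/BRDF gain
#'   field over the whole scene (default 0.10), applied to every band before
#'   sensor noise. Band ratios (vegetation indices) are invariant to it,
#'   plot-mean reflectance is mildly affected, and window-scale image texture
#'   is strongly affected — the canonical reason ratio indices are preferred
#'   over raw reflectance and texture for trait retrieval.
#' @param illum_scale_px correlation length of the gain field, pixels
#'   (default 3).
#' @param micro_amp amplitude of an LAI-independent fine-scale cover field
#'   (default 0.05): at very high spatial resolution some window-scale canopy
#'   texture reflects leaf-scale structure unrelated to LAI.
#' @param soil_moist_sd log-sd of a long-range soil-moisture brightness field
#'   applied to the soil endmember only (default 0.15). Soil-background
#'   variation is largely cancelled by derivative spectra and band
#'   combinations but contaminates single-projection image brightness.
#' @param soil_moist_scale_px correlation length of the moisture field
#'   (default 12).
#' @param wavelengths wavelength grid (default [default_wavelengths()]).
#' @return a `reflectance_cube` with per-plot attributes `plot_roughness` and
#'   `plot_k_ext` (named by plot_id).
#' @export
simulate_cube <- function(layout, truth, stage, seed = 0L,
                          k_ext = 0.5, k_ext_jitter_sd = 0.1,
                          noise_sd = 0.01, roughness_base = 0.12,
                          rough_jitter_sd = 0.08,
                          stripe_amp = 0.25, illum_sd = 0.08,
                          illum_scale_px = 3, micro_amp = 0.05,
                          soil_moist_sd = 0.12, soil_moist_scale_px = 12,
                          wavelengths = default_wavelengths()) {
  truth_s <- truth[truth$stage == stage, , drop = FALSE]
  missing <- setdiff(layout$plot_id, truth_s$plot_id)
  if (length(missing) > 0) {
    stop(sprintf("no ground-truth record at stage %s for plot(s) %s", stage,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  geom <- attr(layout, "geometry") %||% scene_geometry()
  H <- geom$npx_row; W <- geom$npx_col
  stage_idx <- match(stage, lai_stages)
  set.seed(derive_seed(seed, 37L, stage_idx))

  f <- matrix(0, H, W)
  xs <- (seq_len(W) - 0.5) * geom$pixel_size
  ys <- (seq_len(H) - 0.5) * geom$pixel_size
  k_plot <- k_ext * exp(rnorm(nrow(layout), 0, k_ext_jitter_sd))
  names(k_plot) <- layout$plot_id
  rough <- stats::setNames(numeric(nrow(layout)), layout$plot_id)
  for (i in seq_len(nrow(layout))) {
    ring <- layout$polygon[[i]]
    cr <- range(ring[, 1]); rr <- range(ring[, 2])
    cols <- which(xs > cr[1] & xs < cr[2])
    rows <- which(ys > rr[1] & ys < rr[2])
    if (!length(rows) || !length(cols)) stop("plot polygon outside scene", call. = FALSE)
    lai_i <- truth_s$lai[match(layout$plot_id[i], truth_s$plot_id)]
    a_r <- roughness_base / (1 + lai_i) * exp(rnorm(1, 0, rough_jitter_sd))
    rough[i] <- a_r
    f_plot <- 1 - exp(-k_plot[i] * lai_i)
    stripe <- stripe_amp * rep_len(c(1, 1, -1, -1), length(cols)) # 4-px row pitch
    z <- gaussian_random_field(length(rows), length(cols), sigma = 1.5)
    z2 <- gaussian_random_field(length(rows), length(cols), sigma = 1.0)
    # row structure is most visible at intermediate cover and vanishes both
    # on bare soil and at canopy closure
    cover <- f_plot + f_plot * (1 - f_plot) *
      matrix(stripe, length(rows), length(cols), byrow = TRUE) +
      a_r * z + micro_amp * z2
    f[rows, cols] <- pmin(pmax(cover, 0), 1)
  }
  gain <- if (illum_sd > 0) {
    exp(illum_sd * gaussian_random_field(H, W, sigma = illum_scale_px))
  } else {
    matrix(1, H, W)
  }
  moist <- if (soil_moist_sd > 0) {
    exp(soil_moist_sd * gaussian_random_field(H, W, sigma = soil_moist_scale_px))
  } else {
    matrix(1, H, W)
  }

  r_leaf <- leaf_spectrum(wavelengths, stage)
  r_soil <- soil_spectrum(wavelengths, stage)
  B <- length(wavelengths)
  values <- array(0, dim = c(H, W, B))
  soil_frac <- (1 - f) * moist
  for (b in seq_len(B)) {
    band <- gain * (f * r_leaf[b] + soil_frac * r_soil[b])
    if (noise_sd > 0) band <- band + matrix(rnorm(H * W, 0, noise_sd), H, W)
    values[, , b] <- pmin(pmax(band, 0), 1.2)
  }
  cube <- reflectance_cube(values, wavelengths, pixel_size = geom$pixel_size,
                           stage = stage)
  attr(cube, "plot_roughness") <- rough
  attr(cube, "plot_k_ext") <- k_plot
  cube
}

#' Write a cube as an ENVI-style BSQ raster
#'
#' Band-sequential 32-bit float binary with a plain-text ENVI header carrying
#' the wavelength grid; the standard exchange format for hyperspectral cubes.
#' No R raster package is required to round-trip it.
#'
#' @param cube a `reflectance_cube`.
#' @param path output path without extension; writes `path.bsq` and `path.hdr`.
#' @return `path`, invisibly.
#' @export
write_cube_envi <- function(cube, path) {
  d <- dim(cube$values)
  con <- file(paste0(path, ".bsq"), "wb")
  on.exit(close(con))
  for (b in seq_len(d[3])) {
    # BSQ row-major within band
    writeBin(as.vector(t(cube$values[, , b])), con, size = 4, endian = "little")
  }
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0", "file type = ENVI Standard",
    "data type = 4", "interleave = bsq", "byte order = 0",
    sprintf("pixel size = {%s, %s}", cube$pixel_size, cube$pixel_size),
    sprintf("wavelength units = Nanometers"),
    sprintf("wavelength = {%s}", paste(format(cube$wavelengths, trim = TRUE),
                                       collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read a cube written by [write_cube_envi()]
#' @param path path without extension.
#' @return a `reflectance_cube`.
#' @export
read_cube_envi <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  grab <- function(key) {
    line <- grep(paste0("^", key, " ="), hdr, value = TRUE)[1]
    sub(paste0(key, " = "), "", line)
  }
  W <- as.integer(grab("samples")); H <- as.integer(grab("lines"))
  B <- as.integer(grab("bands"))
  wl_txt <- sub(".*\\{", "", sub("\\}.*", "", grab("wavelength")))
  wl <- as.numeric(strsplit(wl_txt, ",")[[1]])
  px_txt <- sub(".*\\{", "", sub("\\}.*", "", grab("pixel size")))
  px <- as.numeric(strsplit(px_txt, ",")[[1]])[1]
  con <- file(paste0(path, ".bsq"), "rb")
  on.exit(close(con))
  values <- array(0, dim = c(H, W, B))
  for (b in seq_len(B)) {
    values[, , b] <- matrix(readBin(con, "numeric", n = H * W, size = 4,
                                    endian = "little"), H, W, byrow = TRUE)
  }
  reflectance_cube(values, wl, pixel_size = px)
}
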