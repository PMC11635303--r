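#' Per-plot mean canopy spectrum
#'
#' Averages the cube over the masked-in pixels whose centers fall inside each
#' plot polygon (unweighted mean), mirroring zonal extraction of canopy
#' reflectance from plot vector files.
#'
#' @param cube a `reflectance_cube`.
#' @param layout a `plot_layout`.
#' @return a `spectrum_set`: list with `reflectance` (plots x bands matrix),
#'   `wavelengths`, `plot_id`, `stage`.
#' @export
plot_mean_spectrum <- function(cube, layout) {
  ctr <- pixel_centers(cube)
  d <- dim(cube$values)
  B <- d[3]
  flat <- matrix(cube$values, d[1] * d[2], B)   # pixel-major (column order)
  refl <- matrix(NA_real_, nrow(layout), B)
  px_grid <- rep(ctr$x, each = d[1])
  py_grid <- rep(ctr$y, times = d[2])
  mask_v <- as.vector(cube$mask)
  for (i in seq_len(nrow(layout))) {
    inside <- points_in_ring(px_grid, py_grid, layout$polygon[[i]]) & mask_v
    if (!any(inside)) {
      stop(sprintf("plot %s has no valid pixels", layout$plot_id[i]), call. = FALSE)
    }
    refl[i, ] <- colMeans(flat[inside, , drop = FALSE])
  }
  structure(list(reflectance = refl, wavelengths = cube$wavelengths,
                 plot_id = layout$plot_id, stage = cube$stage),
            class = "spectrum_set")
}

#' First-order differential spectral reflectance
#'
#' Implements the difference transform exactly as used for feature
#' extraction:
#'
#'   FDSR(i) = (R(i-1) - R(i+1)) / delta_lambda
#'
#' at interior channels, which is -2 times the conventional central
#' difference `(R(i+1) - R(i-1)) / (2 delta_lambda)`. Set
#' `convention = "central"` for the conventional derivative. Endpoints are
#' replicated from the nearest interior value so the output has the input's
#' length.
#'
#' @param spectrum numeric vector (length >= 3).
#' @param delta_lambda sampling interval in nm.
#' @param convention `"paper"` (as printed; default) or `"central"`.
#' @return numeric vector, same length as `spectrum`.
#' @export
fdsr <- function(spectrum, delta_lambda = 4, convention = c("paper", "central")) {
  convention <- match.arg(convention)
  B <- length(spectrum)
  if (B < 3) stop("spectrum must have at least 3 channels", call. = FALSE)
  i <- 2:(B - 1)
  interior <- if (convention == "paper") {
    (spectrum[i - 1] - spectrum[i + 1]) / delta_lambda
  } else {
    (spectrum[i + 1] - spectrum[i - 1]) / (2 * delta_lambda)
  }
  c(interior[1], interior, interior[B - 2])
}

#' Resolve a nominal wavelength to the nearest grid channel
#'
#' Ties (a wavelength equidistant from two channels) resolve to the lower
#' wavelength.
#'
#' @param wavelength_nm nominal wavelength(s).
#' @param grid the wavelength grid.
#' @return integer channel index (vectorized).
#' @export
nearest_channel <- function(wavelength_nm, grid) {
  vapply(wavelength_nm, function(w) {
    d <- abs(grid - w)
    which(d <= min(d) + 1e-12)[1]   # first (lowest-wavelength) minimizer
  }, integer(1))
}

#' Build the spectral feature table (OSR + FDSR + VIs)
#'
#' One row per sample (plot x stage): 125 band-reflectance columns
#' (`OSR_<nm>`), 125 differential columns (`FDSR_<nm>`), and the 30
#' vegetation-index columns, with a `family` attribute tagging every column.
#'
#' @param spectra a `spectrum_set` or list of them (one per stage).
#' @param vi_names which VIs to compute (default: the full 30-entry registry).
#' @param fdsr_convention passed to [fdsr()].
#' @return a `feature_table` data.frame with key columns `plot_id`, `stage`
#'   and a `family` attribute (named character vector over feature columns).
#' @export
build_spectral_features <- function(spectra, vi_names = names(vi_registry()),
                                    fdsr_convention = "paper") {
  if (inherits(spectra, "spectrum_set")) spectra <- list(spectra)
  if (!length(spectra)) stop("no spectra supplied", call. = FALSE)
  tabs <- lapply(spectra, function(s) {
    wl <- s$wavelengths
    dl <- wl[2] - wl[1]
    osr <- s$reflectance
    colnames(osr) <- paste0("OSR_", round(wl))
    fd <- t(apply(osr, 1, fdsr, delta_lambda = dl, convention = fdsr_convention))
    colnames(fd) <- paste0("FDSR_", round(wl))
    vis <- compute_vi_table(s, vi_names)
    data.frame(plot_id = s$plot_id,
               stage = s$stage %||% NA_character_,
               osr, fd, vis, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  family <- c(stats::setNames(rep("OSR", ncol(spectra[[1]]$reflectance)),
                              paste0("OSR_", round(spectra[[1]]$wavelengths))),
              stats::setNames(rep("FDSR", ncol(spectra[[1]]$reflectance)),
                              paste0("FDSR_", round(spectra[[1]]$wavelengths))),
              stats::setNames(rep("VI", length(vi_names)), vi_names))
  attr(out, "family") <- family
  class(out) <- c("feature_table", class(out))
  out
}

#' Feature-family tags of a feature table
#' @param table a `feature_table`.
#' @return named character vector mapping feature columns to families.
#' @export
feature_families <- function(table) attr(table, "family")

#' Bind spectral and texture feature tables into the combined table
#'
#' Joins on (`plot_id`, `stage`) and concatenates the `family` attributes;
#' with the default configuration the result has 125 + 125 + 30 + 28 = 308
#' feature columns.
#'
#' @param spectral,texture `feature_table`s sharing the key columns.
#' @return a combined `feature_table`.
#' @export
bind_feature_tables <- function(spectral, texture) {
  key_s <- paste(spectral$plot_id, spectral$stage)
  key_t <- paste(texture$plot_id, texture$stage)
  idx <- match(key_s, key_t)
  if (anyNA(idx)) stop("texture table does not cover all samples", call. = FALSE)
  tex_cols <- setdiff(colnames(texture), c("plot_id", "stage"))
  out <- cbind(spectral, texture[idx, tex_cols, drop = FALSE])
  attr(out, "family") <- c(attr(spectral, "family"), attr(texture, "family"))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write a feature table as CSV with a JSON family sidecar
#' @param table a `feature_table`.
#' @param path CSV output path; the sidecar is `<path>.families.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  jsonlite::write_json(as.list(attr(table, "family")),
                       paste0(path, ".families.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fam_path <- paste0(path, ".families.json")
  if (file.exists(fam_path)) {
    fam <- unlist(jsonlite::read_json(fam_path))
    attr(out, "family") <- fam
  }
  class(out) <- c("feature_table", class(out))
  out
}
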