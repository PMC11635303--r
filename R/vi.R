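#' Registry of the 30 vegetation indices
#'
#' Each entry is a function of a band accessor `R(wavelength_nm)` returning
#' the formula value, implemented exactly as published (including SPVI's
#' absolute value and RVSI's bracket structure). Nominal wavelengths are
#' resolved to the nearest grid channel by the accessor.
#'
#' @return a named list of 30 functions, in the published order.
#' @export
vi_registry <- function() {
  list(
    DVI   = function(R) R(890) - R(670),
    EVI   = function(R) 2.5 * (R(800) - R(670)) /
      (R(800) + 6 * R(670) - 7.5 * R(450) + 1),
    EVI2  = function(R) 2.5 * (R(800) - R(670)) / (R(800) + 2.4 * R(670) + 1),
    GNDVI = function(R) (R(750) - R(550)) / (R(750) + R(550)),
    GI    = function(R) R(554) / R(677),
    LCI   = function(R) (R(850) - R(710)) / sqrt(R(850) + R(670)),
    MCARI = function(R) ((R(700) - R(670)) - 0.2 * (R(700) - R(550))) *
      (R(700) / R(670)),
    MSR   = function(R) (R(800) / R(670) - 1) / sqrt(R(800) / R(670) + 1),
    MSAVI = function(R) 0.5 * (2 * R(800) + 1 -
      sqrt((2 * R(800) + 1)^2 - 8 * (R(800) - R(670)))),
    MTVI1 = function(R) 1.2 * (1.2 * (R(800) - R(550)) - 2.5 * (R(670) - R(550))),
    MTVI2 = function(R) 1.5 * (1.2 * (R(800) - R(500)) - 2.5 * (R(670) - R(550))) /
      sqrt(2 * (R(800) + 1)^2 - (6 * R(800) - 5 * sqrt(R(670))) - 0.5),
    NDVI  = function(R) (R(800) - R(680)) / (R(800) + R(680)),
    NDRE  = function(R) (R(790) - R(720)) / (R(790) + R(720)),
    NPCI  = function(R) (R(670) - R(460)) / (R(670) + R(460)),
    NDI   = function(R) (R(850) - R(710)) / (R(850) + R(680)),
    NRI   = function(R) (R(570) - R(670)) / (R(570) + R(670)),
    OSAVI = function(R) 1.16 * (R(800) - R(670)) / (R(800) + R(670) + 0.16),
    PSRI  = function(R) (R(680) - R(500)) / R(750),
    PSND  = function(R) (R(800) - R(470)) / (R(800) + R(470)),
    PBI   = function(R) R(810) / R(560),
    RVI   = function(R) R(810) / R(660),
    RDVI  = function(R) (R(800) - R(670)) / sqrt(R(800) + R(670)),
    RASI  = function(R) R(760) / R(500),
    RVSI  = function(R) (R(712) + R(752)) / 2 - R(732),
    SAVI  = function(R) 1.5 * (R(800) - R(670)) / (R(800) + R(670) + 0.5),
    SPVI  = function(R) 0.4 * (3.7 * (R(800) - R(670)) -
      1.2 * abs(R(550) - R(670))),
    TVI   = function(R) 0.5 * (120 * (R(750) - R(550)) - 200 * (R(670) - R(550))),
    TCARI = function(R) 3 * ((R(710) - R(680)) -
      0.2 * (R(700) - R(560)) * (R(710) / R(680))),
    VARI  = function(R) (R(555) - R(680)) / (R(555) + R(680) - R(480)),
    WDRVI = function(R) (0.1 * R(800) - R(670)) / (0.1 * R(800) + R(670))
  )
}

make_band_accessor <- function(reflectance, wavelengths) {
  if (is.matrix(reflectance)) {
    function(wl) reflectance[, nearest_channel(wl, wavelengths)]
  } else {
    function(wl) reflectance[nearest_channel(wl, wavelengths)]
  }
}

#' Compute one vegetation index
#'
#' @param reflectance numeric vector over the wavelength grid, or a samples x
#'   bands matrix.
#' @param wavelengths the wavelength grid (nm).
#' @param vi_name a registry name (see [vi_registry()]).
#' @return the index value (scalar, or vector for matrix input). A non-finite
#'   result (division by zero, negative square-root argument) is an error,
#'   not a silent NaN.
#' @export
compute_vi <- function(reflectance, wavelengths, vi_name) {
  reg <- vi_registry()
  if (!vi_name %in% names(reg)) {
    stop(sprintf("unknown vegetation index '%s'", vi_name), call. = FALSE)
  }
  val <- reg[[vi_name]](make_band_accessor(reflectance, wavelengths))
  if (any(!is.finite(val))) {
    stop(sprintf("vegetation index %s is undefined for this spectrum", vi_name),
         call. = FALSE)
  }
  val
}

#' Compute a block of vegetation indices for a spectrum set
#' @param spectra a `spectrum_set`.
#' @param vi_names registry names (default all 30).
#' @return data.frame, one column per index.
#' @export
compute_vi_table <- function(spectra, vi_names = names(vi_registry())) {
  vals <- lapply(vi_names, function(nm)
    compute_vi(spectra$reflectance, spectra$wavelengths, nm))
  out <- as.data.frame(stats::setNames(vals, vi_names), check.names = FALSE)
  out
}
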