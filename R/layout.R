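#' Field-trial constants
#'
#' The trial crosses two early-maturing potato varieties (Z3, Z5) with a
#' density series (60k/72k/84k tubers per hectare), a nitrogen series
#' (0/112.5/225/337.5 kg/ha pure N) and a potash series (0/495/990 kg/ha
#' K2O). The density and nitrogen series share the standard-fertility control
#' (P2 N2 K1), giving 8 distinct treatments per variety, 16 in total, each
#' replicated 3 times: 48 plots of 32.5 m^2.
#' @keywords internal
treatment_design <- function() {
  per_variety <- rbind(
    # density series at standard N2/K1 (P2N2K1 is the shared control)
    data.frame(density_level = c(60000, 72000, 84000),
               n_level = 225, k_level = 495),
    # nitrogen series at standard density/K1 (N2 row dropped: identical to control)
    data.frame(density_level = 72000,
               n_level = c(0, 112.5, 337.5), k_level = 495),
    # potash series at standard density/N2
    data.frame(density_level = 72000, n_level = 225, k_level = c(0, 990))
  )
  out <- rbind(cbind(variety = "Z3", per_variety),
               cbind(variety = "Z5", per_variety))
  out$variety <- as.character(out$variety)
  out
}

#' Scene geometry defaults
#'
#' Plots are 6.5 m x 5 m (32.5 m^2) on a 6-row x 8-column grid with 0.5 m
#' alleys, rasterized at 0.25 m ground sampling distance (ultra-low-altitude
#' imagery scale). Scene coordinates are planar metres with the origin at the
#' upper-left corner of the raster; rows increase southward.
#' @keywords internal
scene_geometry <- function(pixel_size = 0.25) {
  plot_w <- 6.5; plot_h <- 5; alley <- 0.5
  ncol_plots <- 8L; nrow_plots <- 6L
  width  <- ncol_plots * plot_w + (ncol_plots + 1) * alley
  height <- nrow_plots * plot_h + (nrow_plots + 1) * alley
  list(plot_w = plot_w, plot_h = plot_h, alley = alley,
       ncol_plots = ncol_plots, nrow_plots = nrow_plots,
       pixel_size = pixel_size,
       npx_col = as.integer(round(width / pixel_size)),
       npx_row = as.integer(round(height / pixel_size)))
}

#' Generate the 48-plot trial layout
#'
#' Lays the 16 treatments out as a randomized complete block design: three
#' replicate blocks of 16 plots (two plot rows by eight plot columns each),
#' treatments permuted independently within each block. Polygons are closed
#' axis-aligned rings in scene coordinates (metres).
#'
#' @param seed integer seed controlling the within-block randomization.
#' @param pixel_size ground sampling distance in metres (default 0.25).
#' @return a `plot_layout` data.frame with 48 rows: `plot_id`, `variety`,
#'   `density_level`, `n_level`, `k_level`, `replicate`, and a list-column
#'   `polygon` of closed 5x2 rings, plus a `geometry` attribute.
#' @export
make_layout <- function(seed = 0L, pixel_size = 0.25) {
  geom <- scene_geometry(pixel_size)
  trt <- treatment_design()
  set.seed(derive_seed(seed, 11L))
  rows <- vector("list", 48L)
  plot_id <- 0L
  for (rep_i in 1:3) {
    ord <- sample.int(16L)
    for (k in seq_len(16L)) {
      plot_id <- plot_id + 1L
      slot <- k - 1L                      # 0..15 within the block
      prow <- (rep_i - 1L) * 2L + slot %/% 8L   # plot row 0..5
      pcol <- slot %% 8L                        # plot col 0..7
      x0 <- geom$alley + pcol * (geom$plot_w + geom$alley)
      y0 <- geom$alley + prow * (geom$plot_h + geom$alley)
      ring <- rbind(c(x0, y0), c(x0 + geom$plot_w, y0),
                    c(x0 + geom$plot_w, y0 + geom$plot_h),
                    c(x0, y0 + geom$plot_h), c(x0, y0))
      t <- trt[ord[k], ]
      rows[[plot_id]] <- list(plot_id = plot_id, variety = t$variety,
                              density_level = t$density_level,
                              n_level = t$n_level, k_level = t$k_level,
                              replicate = rep_i, polygon = ring)
    }
  }
  out <- data.frame(
    plot_id = vapply(rows, `[[`, integer(1), "plot_id"),
    variety = vapply(rows, `[[`, character(1), "variety"),
    density_level = vapply(rows, `[[`, numeric(1), "density_level"),
    n_level = vapply(rows, `[[`, numeric(1), "n_level"),
    k_level = vapply(rows, `[[`, numeric(1), "k_level"),
    replicate = vapply(rows, `[[`, integer(1), "replicate"),
    stringsAsFactors = FALSE
  )
  out$polygon <- lapply(rows, `[[`, "polygon")
  attr(out, "geometry") <- geom
  class(out) <- c("plot_layout", class(out))
  out
}

#' Area of a planar ring (shoelace formula)
#' @param ring two-column vertex matrix (closed or open).
#' @return area in squared scene units.
#' @export
ring_area <- function(ring) {
  ring <- as.matrix(ring)
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Write a plot layout as GeoJSON
#'
#' Polygons become GeoJSON Polygon features with the treatment factors as
#' properties, so the layout can be inspected in any GIS.
#'
#' @param layout a `plot_layout`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_layout_geojson <- function(layout, path) {
  features <- lapply(seq_len(nrow(layout)), function(i) {
    ring <- layout$polygon[[i]]
    list(
      type = "Feature",
      properties = list(plot_id = layout$plot_id[i], variety = layout$variety[i],
                        density_level = layout$density_level[i],
                        n_level = layout$n_level[i], k_level = layout$k_level[i],
                        replicate = layout$replicate[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(j) as.numeric(ring[j, ]))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
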