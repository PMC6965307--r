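#' Top-fraction hotspot mask
#'
#' Selects the cells whose value is at least the `(1 - fraction)`
#' quantile of the raster's finite values; ties at the threshold are all
#' included, so the selected count can exceed `round(fraction * n)`.
#'
#' @param raster A [grid_raster()] with at least one finite cell.
#' @param fraction Proportion of cells to keep (default 0.10, the top
#'   decile used for hotspot extraction).
#' @return A logical [grid_raster()] of class `hotspot_mask` (attributes
#'   `fraction` and `threshold`).
#' @export
top_fraction_mask <- function(raster, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop_config("fraction must be in (0, 1]")
  v <- raster$values
  fin <- is.finite(v)
  if (!any(fin)) stop_config("raster has no valid cells")
  thr <- if (fraction == 1) min(v[fin]) else
    quantile(v[fin], probs = 1 - fraction, names = FALSE, type = 7)
  m <- v >= thr
  m[!fin] <- NA
  out <- grid_raster(raster$spec, m * 1)
  out$values <- matrix(as.logical(out$values), raster$spec$n_rows, raster$spec$n_cols)
  class(out) <- c("hotspot_mask", class(out))
  attr(out, "fraction") <- fraction
  attr(out, "threshold") <- thr
  out
}

#' Centroid of a hotspot mask
#'
#' Unweighted arithmetic mean of the selected cells' center coordinates.
#'
#' @param mask A [top_fraction_mask()] result (or any logical raster).
#' @return Named numeric `c(x, y)` in metres.
#' @export
mask_centroid <- function(mask) {
  sel <- which(as.vector(mask$values))
  if (!length(sel)) stop_config("empty hotspot mask")
  cc <- cell_centers(mask$spec)
  c(x = mean(cc$x[sel]), y = mean(cc$y[sel]))
}

#' Centroid shift between two hotspot fields
#'
#' Distance between the centroids of the two rasters' top-fraction
#' masks — comparing where concentration hotspots sit
#' versus where population-exposure-risk hotspots sit.
#'
#' @param raster_a,raster_b [grid_raster()]s on the same grid.
#' @param fraction Hotspot fraction (default 0.10).
#' @return Euclidean distance in km.
#' @export
centroid_shift_km <- function(raster_a, raster_b, fraction = 0.10) {
  if (!same_grid(raster_a, raster_b)) stop_config("rasters are on different grids")
  ca <- mask_centroid(top_fraction_mask(raster_a, fraction))
  cb <- mask_centroid(top_fraction_mask(raster_b, fraction))
  sqrt(sum((ca - cb)^2)) / 1000
}

#' Hotspot centroid-shift table
#'
#' One row per source category comparing the concentration hotspot
#' centroid with the total-population risk hotspot centroid.
#'
#' @param conc Named list of concentration rasters
#'   (`industrial`, `vehicle`, `combined`).
#' @param risk A [risk_stack()].
#' @param fraction Hotspot fraction.
#' @param group Demographic group for the risk side (default `"total"`).
#' @return Data.frame with centroids (m) and the shift distance (km).
#' @export
hotspot_table <- function(conc, risk, fraction = 0.10, group = "total") {
  rows <- lapply(c("industrial", "vehicle", "combined"), function(s) {
    r <- risk_layer(risk, s, group)
    ca <- mask_centroid(top_fraction_mask(conc[[s]], fraction))
    cb <- mask_centroid(top_fraction_mask(r, fraction))
    data.frame(source = s, fraction = fraction,
               conc_x = ca["x"], conc_y = ca["y"],
               risk_x = cb["x"], risk_y = cb["y"],
               shift_km = sqrt(sum((ca - cb)^2)) / 1000,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
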