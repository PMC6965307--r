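#' Inverse-distance-weighted interpolation onto the analysis grid
#'
#' Each cell takes the weighted mean of its `k_neighbors` nearest samples
#' with weights `d^(-power)`, evaluated at the cell center.  A cell whose
#' center lies within `eps` of a sample location takes that sample's value
#' exactly, so the interpolant honours the data.  Values are therefore
#' bounded by the sample range.
#'
#' @param samples Data.frame with columns `x`, `y`, `value` (>= 1 row).
#' @param grid A [grid_spec()].
#' @param power Distance-decay exponent (default 2).
#' @param k_neighbors Number of nearest samples per cell (default 12).
#' @param eps Snap distance (m) for exactness at sample locations.
#' @return A [grid_raster()] on `grid`.
#' @export
idw <- function(samples, grid, power = 2, k_neighbors = 12, eps = 1e-6) {
  samples <- as.data.frame(samples)
  if (!nrow(samples)) stop_config("empty sample set")
  if (k_neighbors < 1) stop_config("k_neighbors must be >= 1")
  key <- paste(samples$x, samples$y)
  if (anyDuplicated(key)) {
    dup <- split(samples$value, key)
    bad <- names(dup)[vapply(dup, function(v) max(v) - min(v) > 0, TRUE)]
    if (length(bad))
      stop_config("conflicting duplicate sample values at (%s)", bad[1])
    first <- !duplicated(key)
    samples <- samples[first, , drop = FALSE]
  }
  cc <- cell_centers(grid)
  vals <- cpp_idw(samples$x, samples$y, samples$value, cc$x, cc$y,
                  power, as.integer(min(k_neighbors, nrow(samples))), eps)
  grid_raster(grid, vals)
}
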