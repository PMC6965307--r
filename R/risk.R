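#' Relative risk of population exposure
#'
#' Per-cell relative exposure risk for one demographic group and one
#' source category:
#' `R_i = (pop_i * C_i) / (mean over the normalization unit of pop * C)`.
#' The unit mean counts every cell of the unit, including uninhabited
#' ones, so the risk surface averages exactly 1 over the unit and values
#' above 1 mark above-average joint exposure.  If the denominator is 0
#' (no population-weighted exposure anywhere in a unit), that unit's risk
#' is set to 0 with a warning.
#'
#' @param pop Population [grid_raster()] (persons per cell, >= 0).
#' @param conc Concentration [grid_raster()] on the same grid (>= 0).
#' @param unit Normalization unit: `NULL` for the whole extent, a logical
#'   vector/matrix selecting the unit's cells, or an integer vector
#'   mapping each cell to a unit id (e.g. an [assign_cells_to_blocks()]
#'   result for per-block normalization; `NA` cells are left `NA`).
#' @return A [grid_raster()] of dimensionless relative risk.
#' @export
relative_risk <- function(pop, conc, unit = NULL) {
  if (!same_grid(pop, conc)) stop_config("population and concentration grids differ")
  p <- as.vector(pop$values)
  c_ <- as.vector(conc$values)
  if (any(p < 0, na.rm = TRUE) || any(c_ < 0, na.rm = TRUE))
    stop_config("negative population or concentration")
  pc <- p * c_
  r <- rep(NA_real_, length(pc))
  if (is.null(unit)) unit <- rep(1L, length(pc))
  if (is.logical(unit)) {
    unit <- as.vector(unit)
    if (!any(unit)) stop_config("empty normalization unit")
    unit <- ifelse(unit, 1L, NA_integer_)
  }
  unit <- as.vector(unit)
  for (u in unique(unit[!is.na(unit)])) {
    cells <- which(unit == u & !is.na(pc))
    if (!length(cells)) next
    denom <- mean(pc[cells])  # n includes zero-population cells
    if (denom == 0) {
      warning(sprintf("zero population-weighted exposure in unit %s; risk set to 0", u),
              call. = FALSE)
      r[cells] <- 0
    } else {
      r[cells] <- pc[cells] / denom
    }
  }
  grid_raster(pop$spec, r)
}

#' All (source, group) relative-risk surfaces
#'
#' Applies [relative_risk()] to every combination of the 7 demographic
#' population layers and the 3 source-category concentration layers.
#'
#' @param pop A [dasymetric_map()] result (7 group layers).
#' @param conc Named list of concentration [grid_raster()]s for
#'   `industrial`, `vehicle`, `combined`.
#' @param unit Passed to [relative_risk()].
#' @return A named list of class `risk_stack` with 21 rasters named
#'   `risk_<source>_<group>`.
#' @export
risk_stack <- function(pop, conc, unit = NULL) {
  sources <- c("industrial", "vehicle", "combined")
  for (g in DEMO_GROUPS) if (is.null(pop[[g]]))
    stop_config("missing population layer: %s", g)
  for (s in sources) if (is.null(conc[[s]]))
    stop_config("missing concentration layer: %s", s)
  out <- list()
  for (s in sources) for (g in DEMO_GROUPS) {
    out[[sprintf("risk_%s_%s", s, g)]] <- relative_risk(pop[[g]], conc[[s]], unit)
  }
  structure(out, class = "risk_stack")
}

risk_layer <- function(stack, source, group) stack[[sprintf("risk_%s_%s", source, group)]]
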