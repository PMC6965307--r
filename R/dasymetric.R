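#' Assign grid cells to census blocks
#'
#' Each cell belongs to the block containing its center (cell-center
#' containment, not area-weighted intersection); cells outside every
#' block stay unassigned.  A cell center claimed by two blocks flags the
#' blocks as overlapping and is an error.
#'
#' @param blocks A [census_blocks()] object with non-overlapping polygons.
#' @param grid A [grid_spec()].
#' @return Integer vector, one entry per cell in column-major order:
#'   the block index, or `NA` for unassigned cells.
#' @export
assign_cells_to_blocks <- function(blocks, grid) {
  cc <- cell_centers(grid)
  assign <- rep(NA_integer_, nrow(cc))
  overlaps <- character(0)
  for (b in seq_len(n_blocks(blocks))) {
    poly <- blocks$polygons[[b]]
    bb <- polygon_bbox(poly)
    cand <- which(cc$x >= bb["xmin"] & cc$x <= bb["xmax"] &
                  cc$y >= bb["ymin"] & cc$y <= bb["ymax"])
    if (!length(cand)) next
    hit <- cand[point_in_polygon(cc$x[cand], cc$y[cand], poly)]
    clash <- hit[!is.na(assign[hit])]
    if (length(clash)) {
      pairs <- unique(sprintf("%s/%s", blocks$counts$id[assign[clash]],
                              blocks$counts$id[b]))
      overlaps <- c(overlaps, pairs)
    }
    assign[hit] <- b
  }
  if (length(overlaps))
    stop_config("overlapping blocks: %s", paste(unique(overlaps), collapse = ", "))
  assign
}

#' Land-use class density fractions
#'
#' Relative population density per land-use class, the ancillary weights
#' of the dasymetric redistribution.  The default taxonomy is
#' 1 = high-density residential (1.0), 2 = low-density residential (0.4),
#' 3 = commercial (0.1), 4 = undeveloped (0), 5 = water (0); the values
#' are configurable placeholders standing in for empirically sampled
#' fractions.
#'
#' @param ... Named fractions, names being land-use class codes.
#' @return Named numeric vector of class fractions.
#' @export
class_fractions <- function(...) {
  f <- c(...)
  if (is.null(names(f)) || any(!nzchar(names(f))))
    stop_config("class fractions must be named by land-use code")
  if (any(f < 0)) stop_config("density fractions must be >= 0")
  if (all(f == 0)) stop_config("at least one class needs a positive fraction")
  f
}

#' @rdname class_fractions
#' @export
default_class_fractions <- function() {
  class_fractions("1" = 1.0, "2" = 0.4, "3" = 0.1, "4" = 0, "5" = 0)
}

#' Dasymetric population mapping
#'
#' Redistributes each block's demographic counts over the block's cells
#' proportionally to the density fraction of each cell's land-use class.
#' If every cell in a block has weight zero but the block is populated,
#' the count falls back to a uniform spread over the block's cells.
#' Block totals are conserved exactly for every demographic group (the
#' pycnophylactic property).
#'
#' @param blocks A [census_blocks()] object.
#' @param landuse A categorical [grid_raster()] of land-use codes on `grid`.
#' @param fractions A [class_fractions()] vector; classes present in the
#'   raster but absent here get fraction 0.
#' @param grid A [grid_spec()].
#' @param cell_map Optional precomputed [assign_cells_to_blocks()] result.
#' @return A named list of class `population_rasters`: one
#'   persons-per-cell [grid_raster()] per demographic group (`total`,
#'   `white`, `black`, `other_races`, `child`, `elderly`, `other_ages`),
#'   with the cell-to-block map attached as attribute `cell_map`.
#' @export
dasymetric_map <- function(blocks, landuse, fractions, grid,
                           cell_map = NULL) {
  if (!isTRUE(all.equal(unclass(landuse$spec), unclass(grid), tolerance = 1e-12)))
    stop_config("land-use raster is not on the analysis grid")
  if (is.null(cell_map)) cell_map <- assign_cells_to_blocks(blocks, grid)
  lu <- as.vector(landuse$values)
  w <- unname(fractions[as.character(lu)])
  w[is.na(w)] <- 0
  ncell <- length(lu)
  out <- lapply(DEMO_GROUPS, function(g) numeric(ncell))
  names(out) <- DEMO_GROUPS
  for (b in seq_len(n_blocks(blocks))) {
    cells <- which(cell_map == b)
    counts <- blocks$counts[b, DEMO_GROUPS]
    if (!length(cells)) {
      if (counts$total > 0)
        stop_config("block %s has population %d but no grid cells (grid too coarse)",
                    blocks$counts$id[b], counts$total)
      next
    }
    wb <- w[cells]
    if (sum(wb) == 0) wb <- rep(1, length(cells))  # uniform fallback
    share <- wb / sum(wb)
    for (g in DEMO_GROUPS) out[[g]][cells] <- share * counts[[g]]
  }
  rasters <- lapply(out, function(v) grid_raster(grid, v))
  structure(rasters, class = "population_rasters", cell_map = cell_map)
}

#' Verify the mass-preserving property of a population mapping
#'
#' @param pop A [dasymetric_map()] result.
#' @param blocks The source [census_blocks()].
#' @return Maximum relative conservation error over all (block, group)
#'   pairs with a positive count.
#' @export
conservation_error <- function(pop, blocks) {
  cell_map <- attr(pop, "cell_map")
  err <- 0
  for (g in DEMO_GROUPS) {
    v <- as.vector(pop[[g]]$values)
    got <- vapply(seq_len(n_blocks(blocks)),
                  function(b) sum(v[which(cell_map == b)]), 0)
    want <- blocks$counts[[g]]
    pos <- want > 0
    if (any(pos)) err <- max(err, max(abs(got[pos] - want[pos]) / want[pos]))
  }
  err
}
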