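#' Analysis grid specification
#'
#' Defines the shared raster geometry used throughout the pipeline: a
#' regular grid of square cells on a local projected plane in metres,
#' origin at the lower-left corner.  Row 1 is the southernmost row and
#' column 1 the westernmost column; cell values are evaluated at cell
#' centers.
#'
#' @param origin_x,origin_y Coordinates (m) of the grid's lower-left corner.
#' @param n_cols,n_rows Number of columns / rows (positive integers).
#' @param cell_size Cell edge length in metres (default 30, the analysis
#'   resolution of the land-use data the framework assumes).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, n_cols, n_rows, cell_size = 30) {
  if (n_cols < 1 || n_rows < 1) stop_config("grid dimensions must be positive")
  if (cell_size <= 0) stop_config("cell_size must be positive")
  structure(
    list(origin_x = origin_x, origin_y = origin_y,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         cell_size = cell_size),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d cols x %d rows @ %g m, origin (%g, %g)\n",
              x$n_cols, x$n_rows, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @param rows,cols Optional row/column indices (default all).
#' @return A data.frame with columns `x`, `y`, `row`, `col`, ordered
#'   column-major to match the raster value matrix.
#' @export
cell_centers <- function(spec, rows = seq_len(spec$n_rows), cols = seq_len(spec$n_cols)) {
  cx <- spec$origin_x + (cols - 0.5) * spec$cell_size
  cy <- spec$origin_y + (rows - 0.5) * spec$cell_size
  data.frame(
    x = rep(cx, each = length(rows)),
    y = rep(cy, times = length(cols)),
    row = rep(rows, times = length(cols)),
    col = rep(cols, each = length(rows)))
}

#' Gridded raster layer
#'
#' A raster is a numeric matrix of `n_rows x n_cols` cell values bound to
#' a [grid_spec()]; `NA` marks nodata.
#'
#' @param spec A [grid_spec()].
#' @param values A matrix of dim `(n_rows, n_cols)`, or a single value to
#'   fill with, or a vector of length `n_rows * n_cols` in column-major
#'   cell order.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(spec, values = NA_real_) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.matrix(values)) {
    if (!all(dim(values) == c(spec$n_rows, spec$n_cols)))
      stop_config("value matrix dim (%d, %d) does not match grid (%d, %d)",
                  nrow(values), ncol(values), spec$n_rows, spec$n_cols)
  } else if (length(values) == 1L) {
    values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  } else if (length(values) == spec$n_rows * spec$n_cols) {
    values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  } else {
    stop_config("values must be scalar, a full-length vector or a matrix")
  }
  structure(list(spec = spec, values = values), class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<grid_raster> %d x %d @ %g m; range [%g, %g], %d nodata\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$cell_size,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(!is.finite(x$values))))
  invisible(x)
}

#' @export
as.matrix.grid_raster <- function(x, ...) x$values

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a$spec), unclass(b$spec), tolerance = 1e-12))
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south).
#'
#' @param raster A [grid_raster()].
#' @param path Output file path.
#' @param nodata Nodata sentinel written for `NA` cells (default -9999).
#' @param digits Significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999, digits = 7) {
  s <- raster$spec
  hdr <- c(
    sprintf("ncols %d", s$n_cols),
    sprintf("nrows %d", s$n_rows),
    sprintf("xllcorner %.10g", s$origin_x),
    sprintf("yllcorner %.10g", s$origin_y),
    sprintf("cellsize %.10g", s$cell_size),
    sprintf("NODATA_value %g", nodata))
  v <- raster$values
  v[!is.finite(v)] <- nodata
  # ASCII rows run north -> south; our matrix row 1 is the south row
  body <- apply(v[rev(seq_len(s$n_rows)), , drop = FALSE], 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1L)
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- tolower(key)
  spec <- grid_spec(val[["xllcorner"]], val[["yllcorner"]],
                    n_cols = val[["ncols"]], n_rows = val[["nrows"]],
                    cell_size = val[["cellsize"]])
  nodata <- val[["nodata_value"]]
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
  m <- m[rev(seq_len(spec$n_rows)), , drop = FALSE]
  m[m == nodata] <- NA_real_
  grid_raster(spec, m)
}
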