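# Minimal planar geometry: everything operates on matrices of (x, y)
# vertices in metres on a local projected plane.

#' Test points for polygon containment
#'
#' Vectorized even-odd (ray casting) point-in-polygon test.  Points that
#' fall exactly on an edge may land on either side; at 30 m cell size
#' against census-block polygons this boundary set has measure zero.
#'
#' @param px,py Point coordinate vectors.
#' @param poly A two-column matrix of polygon vertices (closed or open
#'   ring; the closing edge is implied).
#' @return Logical vector, `TRUE` where the point lies inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  # drop an explicit closing vertex
  n <- nrow(poly)
  if (poly[1, 1] == poly[n, 1] && poly[1, 2] == poly[n, 2]) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), xmax = max(poly[, 1]),
    ymin = min(poly[, 2]), ymax = max(poly[, 2]))
}

#' Total length of a polyline
#' @param coords Two-column vertex matrix (>= 2 rows).
#' @return Length in the coordinate units (m).
#' @export
polyline_length <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 2, nrow(coords) >= 2)
  sum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2))
}

# Split a polyline into sub-segments of length <= seg_len and return their
# midpoints and lengths; used to treat a road as a train of point sources.
densify_polyline <- function(coords, seg_len) {
  stopifnot(seg_len > 0)
  mids <- list(); lens <- list()
  for (i in seq_len(nrow(coords) - 1L)) {
    p0 <- coords[i, ]; p1 <- coords[i + 1L, ]
    L <- sqrt(sum((p1 - p0)^2))
    if (L == 0) next
    nseg <- max(1L, ceiling(L / seg_len))
    t_mid <- (seq_len(nseg) - 0.5) / nseg
    mids[[length(mids) + 1L]] <- cbind(p0[1] + t_mid * (p1[1] - p0[1]),
                                       p0[2] + t_mid * (p1[2] - p0[2]))
    lens[[length(lens) + 1L]] <- rep(L / nseg, nseg)
  }
  if (!length(mids)) stop_config("zero-length polyline")
  list(midpoints = do.call(rbind, mids), lengths = unlist(lens))
}

# Distance from points to a polyline (minimum over segments); vectorized
# over points.
dist_to_polyline <- function(px, py, coords) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(coords) - 1L)) {
    x0 <- coords[i, 1]; y0 <- coords[i, 2]
    dx <- coords[i + 1L, 1] - x0; dy <- coords[i + 1L, 2] - y0
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / L2))
    d2 <- pmin(d2, (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
  }
  sqrt(d2)
}

# --- WKT (POINT / LINESTRING subset used by the inventory table) ---------

wkt_geometry <- function(coords) {
  if (nrow(coords) == 1L) {
    sprintf("POINT (%.10g %.10g)", coords[1, 1], coords[1, 2])
  } else {
    sprintf("LINESTRING (%s)",
            paste(sprintf("%.10g %.10g", coords[, 1], coords[, 2]), collapse = ", "))
  }
}

parse_wkt <- function(txt) {
  txt <- trimws(txt)
  body <- sub("^[A-Z]+\\s*\\(", "", txt)
  body <- sub("\\)\\s*$", "", body)
  pairs <- strsplit(strsplit(body, ",")[[1]], "\\s+")
  pairs <- lapply(pairs, function(p) as.numeric(p[nzchar(p)]))
  m <- do.call(rbind, pairs)
  if (grepl("^POINT", txt) && nrow(m) != 1L) stop_config("malformed WKT point: %s", txt)
  if (grepl("^LINESTRING", txt) && nrow(m) < 2L) stop_config("malformed WKT linestring: %s", txt)
  m
}
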