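#' Convert an annual emission mass to a continuous emission rate
#'
#' Metric tons per year (1 t = 1e6 g) over a 365-day year:
#' `rate = annual_tons * 1e6 / (365 * 86400)` g/s.  Under this convention
#' 237.79 t/yr is 7.54 g/s and 929 t/yr is 29.45 g/s when formatted with
#' [format_emission_rate()] (two decimals, truncated).
#'
#' @param annual_tons Annual emission mass in metric tons (>= 0).
#' @return Emission rate in g/s.
#' @export
tons_per_year_to_g_per_s <- function(annual_tons) {
  if (any(annual_tons < 0)) stop_config("annual_tons must be non-negative")
  annual_tons * 1e6 / (365 * 86400)
}

#' @rdname tons_per_year_to_g_per_s
#' @param rate Emission rate in g/s.
#' @return `format_emission_rate`: the rate truncated (not rounded) to two
#'   decimals, as a character string.
#' @export
format_emission_rate <- function(rate) {
  sprintf("%.2f", trunc(rate * 100 + 1e-9) / 100)
}

# --- sources and inventory ----------------------------------------------

#' Emission sources and inventories
#'
#' A point source is an elevated stack at (x, y); a line source is a road
#' polyline whose annual mass is released uniformly per unit length near
#' ground level.  An emission inventory collects sources of both kinds
#' with a source-category tag (`"industrial"` or `"vehicle"`).
#'
#' @param x,y Source location (m).
#' @param annual_tons Annual emission mass (metric tons, >= 0).
#' @param stack_height Release height above ground (m, >= 0).
#' @param category Source category label.
#' @param id Optional identifier.
#' @return `point_source` / `line_source`: a source object;
#'   `emission_inventory`: an object of class `emission_inventory`.
#' @export
point_source <- function(x, y, annual_tons, stack_height = 10, category = "industrial",
                         id = NULL) {
  if (annual_tons < 0) stop_config("annual_tons must be non-negative")
  if (stack_height < 0) stop_config("stack_height must be non-negative")
  structure(list(coords = cbind(x, y), annual_tons = annual_tons,
                 height = stack_height, category = category,
                 type = "point", id = id),
            class = c("point_source", "emission_source"))
}

#' @rdname point_source
#' @param coords Two-column matrix of polyline vertices (m, >= 2 rows with
#'   positive total length).
#' @param release_height Effective release height of the roadway plume (m).
#' @export
line_source <- function(coords, annual_tons, release_height = 0.5,
                        category = "vehicle", id = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  if (nrow(coords) < 2) stop_config("a line source needs at least 2 vertices")
  if (polyline_length(coords) <= 0) stop_config("line source has zero length")
  if (annual_tons < 0) stop_config("annual_tons must be non-negative")
  structure(list(coords = coords, annual_tons = annual_tons,
                 height = release_height, category = category,
                 type = "line", id = id),
            class = c("line_source", "emission_source"))
}

#' @rdname point_source
#' @param sources A list of `point_source` / `line_source` objects.
#' @export
emission_inventory <- function(sources) {
  stopifnot(all(vapply(sources, inherits, TRUE, "emission_source")))
  ids <- vapply(seq_along(sources), function(i)
    sources[[i]]$id %||% sprintf("src_%03d", i), "")
  if (anyDuplicated(ids)) stop_config("duplicate source ids")
  for (i in seq_along(sources)) sources[[i]]$id <- ids[i]
  structure(list(sources = sources), class = "emission_inventory")
}

#' @export
print.emission_inventory <- function(x, ...) {
  type <- vapply(x$sources, `[[`, "", "type")
  tons <- vapply(x$sources, `[[`, 0, "annual_tons")
  cat(sprintf("<emission_inventory> %d point (%.2f t/yr), %d line (%.2f t/yr)\n",
              sum(type == "point"), sum(tons[type == "point"]),
              sum(type == "line"), sum(tons[type == "line"])))
  invisible(x)
}

inventory_category <- function(inventory, category) {
  keep <- vapply(inventory$sources, function(s) s$category == category, TRUE)
  inventory$sources[keep]
}

#' @rdname point_source
#' @param inventory An `emission_inventory`.
#' @param path File path for the delimited (tab-separated) source table
#'   with columns id, type, category, annual_tons, height_m and a WKT
#'   geometry column.
#' @export
write_inventory <- function(inventory, path) {
  rows <- lapply(inventory$sources, function(s)
    data.frame(id = s$id, type = s$type, category = s$category,
               annual_tons = s$annual_tons, height_m = s$height,
               wkt = wkt_geometry(s$coords)))
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname point_source
#' @export
read_inventory <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  sources <- lapply(seq_len(nrow(tab)), function(i) {
    g <- parse_wkt(tab$wkt[i])
    if (tab$type[i] == "point") {
      point_source(g[1, 1], g[1, 2], tab$annual_tons[i], tab$height_m[i],
                   tab$category[i], id = tab$id[i])
    } else {
      line_source(g, tab$annual_tons[i], tab$height_m[i], tab$category[i],
                  id = tab$id[i])
    }
  })
  emission_inventory(sources)
}

# --- meteorology and the wind rose --------------------------------------

#' Hourly meteorology series
#'
#' @param wind_speed_ms Wind speed (m/s).
#' @param wind_dir_deg Meteorological wind direction: degrees clockwise
#'   from north, the direction the wind blows FROM, in `[0, 360)`.
#' @param stability_class Pasquill stability class, letters `"A"`–`"F"`.
#' @return A data.frame of class `met_series`.
#' @export
met_series <- function(wind_speed_ms, wind_dir_deg, stability_class) {
  if (any(wind_speed_ms < 0)) stop_config("wind speed must be non-negative")
  if (any(wind_dir_deg < 0 | wind_dir_deg >= 360))
    stop_config("wind direction must lie in [0, 360)")
  stability_class <- as.character(stability_class)
  if (!all(stability_class %in% LETTERS[1:6]))
    stop_config("stability classes must be A..F")
  structure(data.frame(wind_speed_ms = wind_speed_ms,
                       wind_dir_deg = wind_dir_deg,
                       stability_class = stability_class),
            class = c("met_series", "data.frame"))
}

#' @rdname met_series
#' @param met A `met_series`.
#' @param path Tab-separated file with columns hour, wind_speed_ms,
#'   wind_dir_deg, stability_class.
#' @export
write_met <- function(met, path) {
  out <- data.frame(hour = seq_len(nrow(met)), met)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname met_series
#' @export
read_met <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  met_series(tab$wind_speed_ms, tab$wind_dir_deg, tab$stability_class)
}

#' Aggregate hourly meteorology into a climatological wind rose
#'
#' Hours calmer than `calm_threshold` are dropped (a Gaussian plume is
#' undefined at zero wind); the remaining records are binned jointly over
#' 16 direction sectors, wind-speed classes and stability classes, and
#' frequencies are normalized over the retained records.  Each cell keeps
#' the mean speed of its member records as the representative speed; the
#' representative direction is the sector midpoint.
#'
#' @param met A [met_series()].
#' @param calm_threshold Calm cut-off in m/s (default 0.5, the usual
#'   regulatory convention).
#' @param speed_breaks Upper-open break points for the speed classes.
#' @return A data.frame of class `wind_rose` with columns `sector`
#'   (1–16, sector 1 centered on north), `mid_dir_deg`, `speed_bin`,
#'   `mean_speed`, `stability`, `freq`; frequencies sum to 1.
#' @export
build_wind_rose <- function(met, calm_threshold = 0.5,
                            speed_breaks = c(0.5, 2.1, 3.6, 5.7, 8.8, 11.1, Inf)) {
  keep <- met$wind_speed_ms >= calm_threshold
  if (!any(keep)) stop_config("no usable meteorology: all records are calm")
  spd <- met$wind_speed_ms[keep]
  dir <- met$wind_dir_deg[keep]
  stab <- met$stability_class[keep]
  sector <- (floor((dir + 11.25) / 22.5) %% 16) + 1
  sbin <- findInterval(spd, speed_breaks, rightmost.closed = FALSE)
  key <- interaction(sector, sbin, stab, drop = TRUE)
  n <- tapply(spd, key, length)
  ms <- tapply(spd, key, mean)
  parts <- do.call(rbind, strsplit(names(n), "\\."))
  rose <- data.frame(
    sector = as.integer(parts[, 1]),
    mid_dir_deg = (as.integer(parts[, 1]) - 1) * 22.5,
    speed_bin = as.integer(parts[, 2]),
    mean_speed = as.numeric(ms),
    stability = parts[, 3],
    freq = as.numeric(n) / sum(n))
  rose <- rose[order(rose$sector, rose$speed_bin, rose$stability), ]
  rownames(rose) <- NULL
  attr(rose, "n_calm") <- sum(!keep)
  attr(rose, "n_used") <- sum(keep)
  class(rose) <- c("wind_rose", "data.frame")
  rose
}

# --- plume kernels ------------------------------------------------------

stability_index <- function(stability) {
  i <- match(toupper(as.character(stability)), LETTERS[1:6])
  if (anyNA(i)) stop_config("unknown stability class")
  as.integer(i)
}

#' Briggs open-country dispersion coefficients
#'
#' Lateral and vertical plume spread (m) as a function of downwind
#' distance for Pasquill stability classes A–F (rural curve family).
#'
#' @param stability Stability class letter(s) `"A"`–`"F"`.
#' @param x Downwind distance(s) in metres.
#' @return A two-column matrix `cbind(sigma_y, sigma_z)`.
#' @export
briggs_sigma <- function(stability, x) {
  n <- max(length(stability), length(x))
  out <- cpp_briggs_sigma(rep_len(stability_index(stability), n), rep_len(x, n))
  colnames(out) <- c("sigma_y", "sigma_z")
  out
}

# wind transport unit vector from a meteorological (blowing-FROM) direction
transport_vector <- function(dir_deg) {
  th <- (dir_deg + 180) * pi / 180
  cbind(ux = sin(th), uy = cos(th))
}

#' Steady-state ground-level concentration from a single point source
#'
#' Gaussian plume with total ground reflection for a receptor at ground
#' level: `C = Q / (pi * u * sy * sz) * exp(-c^2 / (2 sy^2)) *
#' exp(-H^2 / (2 sz^2))`, with `Q` in g/s derived from the source's annual
#' tonnage, Briggs open-country `sy`, `sz`, and the result in µg/m³.
#' Receptors upwind of the source get 0; downwind distances below 1 m are
#' clamped to 1 m; crosswind offsets beyond 12 lateral sigmas contribute 0.
#'
#' @param src A [point_source()].
#' @param receptor Numeric `c(x, y)` or a two-column matrix of receptors (m).
#' @param wind_speed Wind speed u (m/s, > 0).
#' @param wind_dir_deg Meteorological wind direction (blowing from), degrees.
#' @param stability Pasquill class letter.
#' @return Concentration(s) in µg/m³.
#' @export
point_source_concentration <- function(src, receptor, wind_speed, wind_dir_deg,
                                       stability) {
  if (wind_speed <= 0) stop_config("wind speed must be positive")
  if (!is.matrix(receptor)) receptor <- matrix(receptor, ncol = 2)
  q <- tons_per_year_to_g_per_s(src$annual_tons)
  uv <- transport_vector(wind_dir_deg)
  dx <- receptor[, 1] - src$coords[1, 1]
  dy <- receptor[, 2] - src$coords[1, 2]
  xd <- dx * uv[1, "ux"] + dy * uv[1, "uy"]
  cw <- dy * uv[1, "ux"] - dx * uv[1, "uy"]
  out <- numeric(nrow(receptor))
  ok <- xd > 0
  if (any(ok)) {
    xeff <- pmax(xd[ok], 1)
    sg <- briggs_sigma(stability, xeff)
    val <- q * 1e6 / (pi * wind_speed * sg[, 1] * sg[, 2]) *
      exp(-0.5 * (cw[ok] / sg[, 1])^2) * exp(-0.5 * (src$height / sg[, 2])^2)
    val[abs(cw[ok]) > 12 * sg[, 1]] <- 0
    out[ok] <- val
  }
  if (length(out) == 1L) out[[1]] else out
}

#' Steady-state concentration from a road (line) source
#'
#' The polyline is discretized into sub-segments of length at most
#' `seg_len`; each segment is treated as a point source at its midpoint
#' carrying the length-proportional share of the total emission, and the
#' contributions are summed.
#'
#' @param src A [line_source()].
#' @param receptor `c(x, y)` or a two-column matrix (m).
#' @param wind_speed,wind_dir_deg,stability As in
#'   [point_source_concentration()].
#' @param seg_len Maximum segment length (m, default 10).
#' @return Concentration(s) in µg/m³.
#' @export
line_source_concentration <- function(src, receptor, wind_speed, wind_dir_deg,
                                      stability, seg_len = 10) {
  if (!is.matrix(receptor)) receptor <- matrix(receptor, ncol = 2)
  if (src$annual_tons == 0) {
    out <- numeric(nrow(receptor))
    return(if (length(out) == 1L) out[[1]] else out)
  }
  d <- densify_polyline(src$coords, seg_len)
  total_len <- sum(d$lengths)
  out <- numeric(nrow(receptor))
  for (i in seq_len(nrow(d$midpoints))) {
    seg <- point_source(d$midpoints[i, 1], d$midpoints[i, 2],
                        src$annual_tons * d$lengths[i] / total_len,
                        stack_height = src$height, category = src$category)
    out <- out + point_source_concentration(seg, receptor, wind_speed,
                                            wind_dir_deg, stability)
  }
  if (length(out) == 1L) out[[1]] else out
}

# Flatten an inventory category into point-source arrays for the compiled
# field kernel (line sources become midpoint trains).
flatten_sources <- function(sources, seg_len) {
  xs <- numeric(0); ys <- numeric(0); qs <- numeric(0); hs <- numeric(0)
  for (s in sources) {
    q <- tons_per_year_to_g_per_s(s$annual_tons)
    if (s$type == "point") {
      xs <- c(xs, s$coords[1, 1]); ys <- c(ys, s$coords[1, 2])
      qs <- c(qs, q); hs <- c(hs, s$height)
    } else {
      d <- densify_polyline(s$coords, seg_len)
      share <- d$lengths / sum(d$lengths)
      xs <- c(xs, d$midpoints[, 1]); ys <- c(ys, d$midpoints[, 2])
      qs <- c(qs, q * share); hs <- c(hs, rep(s$height, length(share)))
    }
  }
  list(x = xs, y = ys, q = qs, h = hs)
}

#' Annual-mean concentration field under a wind rose
#'
#' Frequency-weights the steady-state plume over every wind-rose cell
#' (representative speed = cell mean, direction = sector midpoint) and
#' sums over sources, producing per-category annual means at discrete
#' receptors plus their sum as `combined`.  Within a (sector, stability)
#' slice the plume is exactly proportional to `1/u`, so speed classes are
#' collapsed analytically before the kernel loop.
#'
#' @param inventory An [emission_inventory()].
#' @param rose A [build_wind_rose()] result.
#' @param receptors Data.frame or matrix with receptor `x`, `y` (m).
#' @param seg_len Line-source discretization length (m) used for the
#'   field computation.
#' @return A data.frame of class `concentration_field` with columns `x`,
#'   `y`, `industrial`, `vehicle`, `combined` (µg/m³).
#' @export
annual_mean_field <- function(inventory, rose, receptors, seg_len = 10) {
  receptors <- as.data.frame(receptors)
  if (!nrow(receptors)) stop_config("no receptors")
  if (abs(sum(rose$freq) - 1) > 1e-9) stop_config("rose frequencies must sum to 1")
  # collapse speed bins: C  ~  freq / u  within (sector, stability)
  key <- interaction(rose$sector, rose$stability, drop = TRUE)
  w <- tapply(rose$freq / rose$mean_speed, key, sum)
  sector <- as.integer(vapply(strsplit(names(w), "\\."), `[`, "", 1L))
  stab <- vapply(strsplit(names(w), "\\."), `[`, "", 2L)
  uv <- transport_vector((sector - 1) * 22.5)
  out <- data.frame(x = receptors$x, y = receptors$y)
  for (cat in c("industrial", "vehicle")) {
    srcs <- inventory_category(inventory, cat)
    if (!length(srcs)) {
      out[[cat]] <- numeric(nrow(receptors))
      next
    }
    fl <- flatten_sources(srcs, seg_len)
    out[[cat]] <- cpp_plume_field(fl$x, fl$y, fl$q, fl$h,
                                  receptors$x, receptors$y,
                                  uv[, "ux"], uv[, "uy"],
                                  stability_index(stab), as.numeric(w))
  }
  out$combined <- out$industrial + out$vehicle
  class(out) <- c("concentration_field", "data.frame")
  out
}

#' Receptor locations on a subsampled analysis grid
#'
#' Discrete receptors are placed at the centers of every `stride`-th cell
#' in both directions, emulating a coarse dispersion-model receptor net
#' whose output is then interpolated back onto the full grid.
#'
#' @param spec A [grid_spec()].
#' @param stride Subsampling stride in cells (default 5).
#' @return Data.frame with receptor `x`, `y` (m).
#' @export
receptor_grid <- function(spec, stride = 5) {
  rows <- seq(1L, spec$n_rows, by = stride)
  cols <- seq(1L, spec$n_cols, by = stride)
  cell_centers(spec, rows, cols)[, c("x", "y")]
}

#' @rdname annual_mean_field
#' @param field A `concentration_field`.
#' @param path Tab-separated output path.
#' @export
write_concentration_field <- function(field, path) {
  write.table(as.data.frame(field), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname annual_mean_field
#' @export
read_concentration_field <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE)
  class(out) <- c("concentration_field", "data.frame")
  out
}
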