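DEMO_GROUPS <- c("total", "white", "black", "other_races",
                 "child", "elderly", "other_ages")
RACE_GROUPS <- c("white", "black", "other_races")
AGE_GROUPS <- c("child", "elderly", "other_ages")

#' Census blocks with demographic counts
#'
#' Source polygons for dasymetric mapping.  Every block carries a total
#' population and its decomposition by race (white, black, other races)
#' and by age (child, elderly, other age groups); both decompositions
#' must sum to the block total.
#'
#' @param polygons List of two-column vertex matrices (one polygon per
#'   block, closed or open rings).
#' @param counts Data.frame with one row per block and columns `total`,
#'   `white`, `black`, `other_races`, `child`, `elderly`, `other_ages`
#'   (and optionally `id`).
#' @return An object of class `census_blocks`.
#' @export
census_blocks <- function(polygons, counts) {
  counts <- as.data.frame(counts)
  if (length(polygons) != nrow(counts))
    stop_config("polygons (%d) and count rows (%d) differ", length(polygons),
                nrow(counts))
  missing <- setdiff(DEMO_GROUPS, names(counts))
  if (length(missing)) stop_config("missing count columns: %s",
                                   paste(missing, collapse = ", "))
  if (is.null(counts$id)) counts$id <- sprintf("blk_%04d", seq_len(nrow(counts)))
  if (any(as.matrix(counts[DEMO_GROUPS]) < 0))
    stop_config("negative population counts")
  if (any(rowSums(counts[RACE_GROUPS]) != counts$total))
    stop_config("race counts do not sum to block totals")
  if (any(rowSums(counts[AGE_GROUPS]) != counts$total))
    stop_config("age counts do not sum to block totals")
  structure(list(polygons = polygons, counts = counts[c("id", DEMO_GROUPS)]),
            class = "census_blocks")
}

#' @export
print.census_blocks <- function(x, ...) {
  cat(sprintf("<census_blocks> %d blocks, %d persons\n",
              length(x$polygons), sum(x$counts$total)))
  invisible(x)
}

n_blocks <- function(blocks) length(blocks$polygons)

#' Read / write census blocks as GeoJSON
#'
#' One `Feature` per block with a `Polygon` geometry and the demographic
#' counts as properties.
#'
#' @param blocks A [census_blocks()] object.
#' @param path File path.
#' @return `write_blocks_geojson`: `path` invisibly;
#'   `read_blocks_geojson`: a `census_blocks` object.
#' @export
write_blocks_geojson <- function(blocks, path) {
  features <- lapply(seq_len(n_blocks(blocks)), function(i) {
    poly <- blocks$polygons[[i]]
    n <- nrow(poly)
    if (poly[1, 1] != poly[n, 1] || poly[1, 2] != poly[n, 2])
      poly <- rbind(poly, poly[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(poly, 1, as.list)))),
         properties = as.list(blocks$counts[i, , drop = FALSE]))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = features),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_blocks_geojson
#' @export
read_blocks_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polygons <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  })
  counts <- do.call(rbind, lapply(fc$features, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE)))
  census_blocks(polygons, counts)
}
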