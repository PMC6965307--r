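#' Classification break scheme
#'
#' An ordered set of class intervals `(lower, upper]` (the lowest class
#' also contains its lower bound) with one label per class.
#'
#' @param breaks Strictly increasing numeric vector of length
#'   `n_classes + 1` (outer bounds included).
#' @param labels Character vector of class labels, one per interval; a
#'   default `Low ... Extreme High` ladder is supplied for 2–6 classes.
#' @return An object of class `break_scheme`.
#' @export
break_scheme <- function(breaks, labels = NULL) {
  if (any(diff(breaks) <= 0)) stop_config("breaks must be strictly increasing")
  k <- length(breaks) - 1L
  if (is.null(labels)) labels <- default_labels(k)
  if (length(labels) != k)
    stop_config("%d labels for %d classes", length(labels), k)
  structure(list(breaks = as.numeric(breaks), labels = labels),
            class = "break_scheme")
}

default_labels <- function(k) {
  ladder <- switch(as.character(k),
    "2" = c("Low", "High"),
    "3" = c("Low", "Med", "High"),
    "4" = c("Low", "Low-Med", "Med", "High"),
    "5" = c("Low", "Low-Med", "Med", "High", "Extreme High"),
    "6" = c("Low", "Low-Med", "Med", "High-Med", "High", "Extreme High"),
    paste0("class_", seq_len(k)))
  ladder
}

#' @export
print.break_scheme <- function(x, ...) {
  k <- length(x$labels)
  cat("<break_scheme>\n")
  for (i in seq_len(k))
    cat(sprintf("  %-13s (%g, %g]\n", x$labels[i], x$breaks[i], x$breaks[i + 1]))
  invisible(x)
}

#' Natural-breaks (Fisher-Jenks) classification
#'
#' Exact optimal partition of the values into `k` classes minimising the
#' total within-class sum of squared deviations, via dynamic programming
#' (not the heuristic variant).  For large inputs a seeded random
#' subsample of `sample_n` values is classified instead; the result is
#' deterministic for identical inputs.
#'
#' @param values Numeric vector (non-finite entries dropped); needs at
#'   least `k` distinct values.
#' @param k Number of classes (>= 2).
#' @param labels Optional class labels.
#' @param sample_n Subsample size cap for large inputs (default 2000).
#' @return A [break_scheme()] whose inner breaks are midpoints between
#'   adjacent class-boundary data values.
#' @export
jenks_breaks <- function(values, k, labels = NULL, sample_n = 2000) {
  v <- values[is.finite(values)]
  if (k < 2) stop_config("k must be >= 2")
  if (length(unique(v)) < k)
    stop_config("need at least %d distinct values, have %d", k, length(unique(v)))
  if (length(v) > sample_n) {
    v <- with_seed(194803L, sample(v, sample_n))
    # keep the extremes so the scheme spans the data
    v <- c(v, min(values[is.finite(values)]), max(values[is.finite(values)]))
    if (length(unique(v)) < k) v <- values[is.finite(values)]
  }
  x <- sort(v)
  ends <- cpp_jenks_ends(x, as.integer(k))
  inner <- (x[ends[-k]] + x[ends[-k] + 1L]) / 2
  break_scheme(c(x[1], inner, x[length(x)]), labels)
}

# total within-class SSD of a partition given by class end indices
jenks_ssd <- function(x, ends) {
  starts <- c(1L, head(ends, -1L) + 1L)
  sum(vapply(seq_along(ends), function(i) {
    seg <- x[starts[i]:ends[i]]
    sum((seg - mean(seg))^2)
  }, 0))
}

#' Classify a raster by a break scheme
#'
#' Maps each finite cell to the class whose `(lower, upper]` interval
#' contains it (the lowest class is closed on the left).  Values outside
#' the scheme's range are assigned to the nearest boundary class with a
#' warning; `NA` cells stay `NA`.
#'
#' @param raster A [grid_raster()].
#' @param scheme A [break_scheme()].
#' @return A [grid_raster()] of integer class codes `1..k`, with the
#'   labels attached as attribute `labels`.
#' @export
classify_raster <- function(raster, scheme) {
  v <- as.vector(raster$values)
  k <- length(scheme$labels)
  cls <- rep(NA_integer_, length(v))
  fin <- is.finite(v)
  # (lower, upper] intervals; lowest class closed on the left
  cls[fin] <- findInterval(v[fin], scheme$breaks, left.open = TRUE,
                           rightmost.closed = FALSE)
  cls[fin & v == scheme$breaks[1]] <- 1L
  low <- fin & v < scheme$breaks[1]
  high <- fin & v > scheme$breaks[k + 1]
  if (any(low) || any(high)) {
    warning(sprintf("%d cell(s) outside the scheme range assigned to boundary classes",
                    sum(low) + sum(high)), call. = FALSE)
    cls[low] <- 1L
    cls[high] <- k
  }
  out <- grid_raster(raster$spec, cls)
  attr(out, "labels") <- scheme$labels
  out
}

#' Frozen reference break schemes
#'
#' Fixed four-level SO2 concentration classes (µg/m³) and six-level
#' relative-risk classes, shipped so that maps from different runs stay
#' comparable; data-driven alternatives come from [jenks_breaks()].
#'
#' @return A [break_scheme()].
#' @export
default_concentration_scheme <- function() {
  break_scheme(c(0, 0.28, 0.35, 0.49, 1.50),
               c("Low", "Low-Med", "Med", "High"))
}

#' @rdname default_concentration_scheme
#' @export
default_risk_scheme <- function() {
  break_scheme(c(0, 1.00, 1.29, 1.66, 2.21, 3.07, 30.60),
               c("Low", "Low-Med", "Med", "High-Med", "High", "Extreme High"))
}

#' Legend table for a break scheme
#' @param scheme A [break_scheme()].
#' @return Data.frame with class code, label, lower and upper bounds.
#' @export
scheme_legend <- function(scheme) {
  k <- length(scheme$labels)
  data.frame(class = seq_len(k), label = scheme$labels,
             lower = scheme$breaks[-(k + 1)], upper = scheme$breaks[-1])
}
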