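# Desk-scale fixture builders shared across test files.

tiny_config <- function(seed = 1L, ...) {
  args <- list(extent_km = c(3, 3), grid_resolution_m = 100,
               n_point_sources = 5, n_road_polylines = 2,
               n_blocks = 20, total_population = 5000,
               n_met_hours = 400, rng_seed = seed)
  do.call(scenario_config, utils::modifyList(args, list(...)))
}

tiny_params <- function(cfg, ...) {
  pipeline_config(seed = cfg$rng_seed, scenario = cfg,
                  receptor_stride = 3, seg_len = 50, ...)
}

# Independent hand-coded Gaussian-plume evaluation used as the oracle for
# the dispersion kernels: Briggs open-country sigmas and the reflected
# ground-level plume, written directly from the closed form.
oracle_sigma <- function(stab, x) {
  fy <- 1 / sqrt(1 + 0.0001 * x)
  switch(stab,
    A = c(0.22 * x * fy, 0.20 * x),
    B = c(0.16 * x * fy, 0.12 * x),
    C = c(0.11 * x * fy, 0.08 * x / sqrt(1 + 0.0002 * x)),
    D = c(0.08 * x * fy, 0.06 * x / sqrt(1 + 0.0015 * x)),
    E = c(0.06 * x * fy, 0.03 * x / (1 + 0.0003 * x)),
    F = c(0.04 * x * fy, 0.016 * x / (1 + 0.0003 * x)))
}

oracle_plume <- function(q_gs, u, stab, xd, cross = 0, H = 0) {
  if (xd <= 0) return(0)
  s <- oracle_sigma(stab, max(xd, 1))
  q_gs * 1e6 / (pi * u * s[1] * s[2]) *
    exp(-0.5 * (cross / s[1])^2) * exp(-0.5 * (H / s[2])^2)
}

# annual tonnage that corresponds to a given continuous rate in g/s
tons_for_rate <- function(q_gs) q_gs * 365 * 86400 / 1e6

# brute-force all-pairs IDW used as the interpolation oracle
oracle_idw <- function(samples, grid, power, k) {
  cc <- cell_centers(grid)
  vapply(seq_len(nrow(cc)), function(i) {
    d <- sqrt((samples$x - cc$x[i])^2 + (samples$y - cc$y[i])^2)
    ord <- order(d)[seq_len(min(k, nrow(samples)))]
    if (d[ord[1]] <= 1e-6) return(samples$value[ord[1]])
    w <- d[ord]^(-power)
    sum(w * samples$value[ord]) / sum(w)
  }, 0)
}

# exhaustive minimum within-class SSD over all ordered k-partitions
oracle_jenks_ssd <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssd <- function(seg) sum((seg - mean(seg))^2)
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(cuts))) {
    ends <- c(cuts[, j], n)
    starts <- c(1, head(ends, -1) + 1)
    tot <- sum(vapply(seq_len(k), function(i) ssd(x[starts[i]:ends[i]]), 0))
    if (tot < best) best <- tot
  }
  best
}

partition_ssd <- function(x, breaks) {
  x <- sort(x)
  cls <- findInterval(x, breaks, left.open = TRUE, rightmost.closed = FALSE)
  cls[x <= breaks[1]] <- 1
  cls[x > breaks[length(breaks)]] <- length(breaks) - 1
  sum(vapply(split(x, cls), function(seg) sum((seg - mean(seg))^2), 0))
}
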