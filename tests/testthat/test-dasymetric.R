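square <- function(x0, x1, y0, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))

block_counts <- function(total, ...) {
  extra <- list(...)
  base <- data.frame(total = total, white = total, black = 0L, other_races = 0L,
                     child = 0L, elderly = 0L, other_ages = total)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

test_that("ray-casting containment agrees with an independent implementation", {
  set.seed(21)
  for (i in 1:10) {
    nv <- sample(3:9, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 2, 10)
    poly <- cbind(rad * cos(ang), rad * sin(ang))  # star-shaped, irregular
    px <- runif(200, -12, 12); py <- runif(200, -12, 12)
    got <- point_in_polygon(px, py, poly)
    ref <- as.logical(mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py)))
    expect_identical(got, ref)
  }
})

test_that("cells are assigned to the blocks containing their centers", {
  g <- grid_spec(0, 0, 10, 10, 10)
  one <- census_blocks(list(square(0, 100, 0, 100)), block_counts(10L))
  expect_true(all(assign_cells_to_blocks(one, g) == 1L))

  two <- census_blocks(list(square(0, 50, 0, 100), square(50, 100, 0, 100)),
                       rbind(block_counts(4L), block_counts(6L)))
  amap <- matrix(assign_cells_to_blocks(two, g), 10, 10)
  cc <- cell_centers(g)
  expect_true(all(amap[, 1:5] == 1L))
  expect_true(all(amap[, 6:10] == 2L))

  # irregular blocks against a per-cell point-in-polygon oracle
  tri1 <- cbind(c(0, 100, 0), c(0, 0, 100))
  tri2 <- cbind(c(100, 100, 10), c(5, 100, 100))
  blk <- census_blocks(list(tri1, tri2), rbind(block_counts(3L), block_counts(3L)))
  got <- assign_cells_to_blocks(blk, g)
  ref <- rep(NA_integer_, nrow(cc))
  for (b in 1:2) {
    inb <- as.logical(mgcv::in.out(rbind(blk$polygons[[b]], blk$polygons[[b]][1, ]),
                                   cbind(cc$x, cc$y)))
    ref[inb] <- b
  }
  expect_identical(got, ref)
})

test_that("overlapping blocks are reported as an error naming the pair", {
  g <- grid_spec(0, 0, 10, 10, 10)
  ov <- census_blocks(list(square(0, 60, 0, 100), square(40, 100, 0, 100)),
                      rbind(block_counts(4L), block_counts(6L)))
  expect_error(assign_cells_to_blocks(ov, g), "overlapping blocks: blk_0001/blk_0002")
})

test_that("dasymetric allocation follows the land-use density fractions", {
  # one block of 10 cells: 6 urban cells (fraction 0.9), 4 water (fraction 0)
  g <- grid_spec(0, 0, 10, 1, 10)
  lu <- grid_raster(g, c(rep(1, 6), rep(5, 4)))
  blk <- census_blocks(list(square(0, 100, 0, 10)), block_counts(100L))
  pop <- dasymetric_map(blk, lu, class_fractions("1" = 0.9, "5" = 0), g)
  expect_equal(as.vector(pop$total$values), c(rep(100 / 6, 6), rep(0, 4)))

  # single class everywhere: the areal-weighting limit
  lu2 <- grid_raster(g, rep(2, 10))
  pop2 <- dasymetric_map(blk, lu2, class_fractions("2" = 0.4), g)
  expect_equal(as.vector(pop2$total$values), rep(10, 10))

  # all-zero weights fall back to a uniform spread
  g5 <- grid_spec(0, 0, 5, 1, 10)
  lu5 <- grid_raster(g5, rep(4, 5))
  blk5 <- census_blocks(list(square(0, 50, 0, 10)), block_counts(50L))
  pop5 <- dasymetric_map(blk5, lu5, class_fractions("1" = 1, "4" = 0), g5)
  expect_equal(as.vector(pop5$total$values), rep(10, 5))
})

test_that("a populated block with no cells is a grid-resolution error", {
  g <- grid_spec(0, 0, 10, 1, 10)
  lu <- grid_raster(g, rep(1, 10))
  blk <- census_blocks(list(square(0, 98, 0, 10), square(98, 99.5, 0, 10)),
                       rbind(block_counts(10L), block_counts(5L)))
  expect_error(dasymetric_map(blk, lu, class_fractions("1" = 1), g),
               "no grid cells")
})

test_that("block totals are conserved for every demographic group", {
  for (seed in 1:10) {
    scn <- generate_scenario(tiny_config(seed))
    pop <- dasymetric_map(scn$blocks, scn$landuse, default_class_fractions(),
                          scn$grid)
    expect_lt(conservation_error(pop, scn$blocks), 1e-6)
    for (g in c("total", "black", "elderly"))
      expect_true(all(pop[[g]]$values >= 0))
  }
})

test_that("raising a class fraction never starves that class's cells", {
  g <- grid_spec(0, 0, 10, 1, 10)
  lu <- grid_raster(g, c(rep(1, 5), rep(2, 5)))
  blk <- census_blocks(list(square(0, 100, 0, 10)), block_counts(100L))
  lo <- dasymetric_map(blk, lu, class_fractions("1" = 1, "2" = 0.2), g)
  hi <- dasymetric_map(blk, lu, class_fractions("1" = 1, "2" = 0.6), g)
  expect_true(all(hi$total$values[, 6:10] >= lo$total$values[, 6:10]))
})

test_that("blocks round-trip through GeoJSON", {
  scn <- generate_scenario(tiny_config(13))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_blocks_geojson(scn$blocks, path)
  back <- read_blocks_geojson(path)
  expect_identical(back$counts, scn$blocks$counts)
  for (i in seq_along(back$polygons)) {
    a <- scn$blocks$polygons[[i]]
    b <- back$polygons[[i]][seq_len(nrow(a)), , drop = FALSE]
    expect_equal(unname(b), unname(a), tolerance = 1e-9)
  }
})
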