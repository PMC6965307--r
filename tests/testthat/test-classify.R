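test_that("natural breaks separate obvious clusters and saturated inputs", {
  s <- jenks_breaks(c(1, 1, 1, 9, 9, 9), 2)
  cls <- classify_raster(grid_raster(grid_spec(0, 0, 6, 1, 10), c(1, 1, 1, 9, 9, 9)), s)
  expect_equal(as.vector(cls$values), c(1, 1, 1, 2, 2, 2))

  s6 <- jenks_breaks(1:6, 6)
  cls6 <- classify_raster(grid_raster(grid_spec(0, 0, 6, 1, 10), 1:6), s6)
  expect_equal(as.vector(cls6$values), 1:6)

  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct values")
  expect_error(jenks_breaks(1:5, 1), "k must be")
})

test_that("returned partitions achieve the exhaustive-enumeration optimum", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 1)
    if (length(unique(x)) < k) next
    s <- jenks_breaks(x, k)
    expect_equal(partition_ssd(x, s$breaks), oracle_jenks_ssd(x, k),
                 tolerance = 1e-9)
  }
})

test_that("classification uses half-open (lower, upper] intervals", {
  s <- break_scheme(c(0, 1, 2), c("Low", "High"))
  g <- grid_spec(0, 0, 5, 1, 10)
  cls <- classify_raster(grid_raster(g, c(0, 0.5, 1, 1.5, 2)), s)
  # a value exactly at an inner break falls in the lower interval's class
  expect_equal(as.vector(cls$values), c(1, 1, 1, 2, 2))

  # constant raster: a single class everywhere
  sc <- break_scheme(c(0, 3, 6), c("Low", "High"))
  const <- classify_raster(grid_raster(g, 2), sc)
  expect_true(all(const$values == 1))

  # out-of-range values go to the nearest boundary class with a warning
  expect_warning(out <- classify_raster(grid_raster(g, c(-1, 0.5, 1, 1.5, 9)), s),
                 "outside the scheme range")
  expect_equal(as.vector(out$values), c(1, 1, 1, 2, 2))

  # classification is total: every finite cell gets exactly one label
  set.seed(3)
  vals <- runif(5, 0, 2)
  cls2 <- classify_raster(grid_raster(g, vals), s)
  expect_true(all(cls2$values %in% 1:2))
})

test_that("toy raster labels match a direct interval lookup", {
  set.seed(15)
  vals <- runif(30, 0, 10)
  s <- jenks_breaks(vals, 3)
  g <- grid_spec(0, 0, 6, 5, 10)
  got <- as.vector(classify_raster(grid_raster(g, vals), s)$values)
  ref <- vapply(vals, function(v) {
    if (v <= s$breaks[2]) 1 else if (v <= s$breaks[3]) 2 else 3
  }, 0)
  expect_identical(got, ref)
})

test_that("the frozen reference schemes expose the documented ladders", {
  cs <- default_concentration_scheme()
  expect_identical(cs$labels, c("Low", "Low-Med", "Med", "High"))
  expect_identical(length(cs$breaks), 5L)
  rs <- default_risk_scheme()
  expect_identical(rs$labels,
                   c("Low", "Low-Med", "Med", "High-Med", "High", "Extreme High"))
  leg <- scheme_legend(rs)
  expect_identical(nrow(leg), 6L)
  expect_true(all(diff(leg$lower) > 0))
})
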