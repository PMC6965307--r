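test_that("annual tonnage converts to g/s under metric tons and a 365-day year", {
  expect_equal(tons_per_year_to_g_per_s(237.79), 237.79e6 / (365 * 86400))
  expect_identical(format_emission_rate(tons_per_year_to_g_per_s(237.79)), "7.54")
  expect_identical(format_emission_rate(tons_per_year_to_g_per_s(929)), "29.45")
  expect_identical(format_emission_rate(tons_per_year_to_g_per_s(0)), "0.00")
  expect_error(tons_per_year_to_g_per_s(-1), "non-negative")
})

test_that("wind rose bins, drops calms and normalizes over retained hours", {
  one <- build_wind_rose(met_series(3, 270, "D"))
  expect_identical(nrow(one), 1L)
  expect_equal(one$freq, 1)
  expect_equal(one$mid_dir_deg, 270)
  expect_equal(one$mean_speed, 3)

  # balanced directions: each sector frequency exactly 1/16 by the count oracle
  dirs <- rep((0:15) * 22.5, each = 10)
  met <- met_series(rep(3, 160), dirs, rep("D", 160))
  rose <- build_wind_rose(met)
  by_sector <- tapply(rose$freq, rose$sector, sum)
  expect_equal(as.vector(by_sector), rep(1 / 16, 16), tolerance = 1e-12)

  # 10% calms are dropped and frequencies renormalize to 1
  spd <- c(rep(0.2, 10), rep(4, 90))
  met <- met_series(spd, runif(100, 0, 359.9), sample(LETTERS[1:6], 100, TRUE))
  rose <- build_wind_rose(met)
  expect_equal(sum(rose$freq), 1, tolerance = 1e-12)
  expect_identical(attr(rose, "n_calm"), 10L)

  expect_error(build_wind_rose(met_series(c(0.1, 0.3), c(10, 20), c("D", "D"))),
               "no usable meteorology")
})

test_that("point-source plume matches an independent closed-form evaluation", {
  src <- point_source(0, 0, tons_for_rate(10), stack_height = 0)
  # receptor 1000 m downwind on the centerline, wind from the west (270 deg)
  got <- point_source_concentration(src, c(1000, 0), 5, 270, "D")
  expect_equal(got, oracle_plume(10, 5, "D", 1000), tolerance = 1e-12)
  # elevated release, off-centerline, a different stability class
  src2 <- point_source(0, 0, tons_for_rate(3.7), stack_height = 25)
  got2 <- point_source_concentration(src2, c(800, 120), 2.5, 270, "B")
  expect_equal(got2, oracle_plume(3.7, 2.5, "B", 800, cross = 120, H = 25),
               tolerance = 1e-12)
})

test_that("plume respects upwind zeros and is linear in the emission rate", {
  src <- point_source(0, 0, 100, stack_height = 10)
  expect_identical(point_source_concentration(src, c(-500, 0), 5, 270, "D"), 0)
  src2 <- point_source(0, 0, 200, stack_height = 10)
  r <- matrix(c(400, 50, 1500, -200), 2, byrow = TRUE)
  expect_equal(point_source_concentration(src2, r, 5, 270, "D"),
               2 * point_source_concentration(src, r, 5, 270, "D"),
               tolerance = 1e-14)
})

test_that("line-source discretization converges and matches adaptive quadrature", {
  # straight crosswind line, wind from the west
  line <- line_source(cbind(c(0, 0), c(-400, 400)), tons_for_rate(5),
                      release_height = 0)
  expect_identical(line_source_concentration(
    line_source(cbind(c(0, 0), c(-400, 400)), 0), c(300, 0), 4, 270, "D"), 0)

  rec <- c(300, 40)
  c10 <- line_source_concentration(line, rec, 4, 270, "D", seg_len = 10)
  c5 <- line_source_concentration(line, rec, 4, 270, "D", seg_len = 5)
  expect_lt(abs(c5 - c10) / c10, 0.01)

  quad <- stats::integrate(function(yy) {
    vapply(yy, function(y) oracle_plume(5 / 800, 4, "D", rec[1], rec[2] - y), 0)
  }, -400, 400, rel.tol = 1e-10)$value
  expect_lt(abs(c10 - quad) / quad, 0.01)
})

test_that("annual mean field obeys additivity, superposition and rose weighting", {
  met <- met_series(c(3, 5, 2, 4), c(270, 180, 90, 300), c("D", "B", "E", "D"))
  rose <- build_wind_rose(met)
  rec <- expand.grid(x = seq(100, 900, by = 400), y = seq(100, 900, by = 400))
  p1 <- point_source(200, 500, 50, stack_height = 5, id = "a")
  p2 <- point_source(700, 300, 80, stack_height = 12, id = "b")
  road <- line_source(cbind(c(0, 1000), c(450, 520)), 120, id = "r")

  only_ind <- annual_mean_field(emission_inventory(list(p1, p2)), rose, rec)
  expect_true(all(only_ind$vehicle == 0))
  expect_equal(only_ind$combined, only_ind$industrial)

  both <- annual_mean_field(emission_inventory(list(p1, p2, road)), rose, rec)
  expect_equal(both$combined, both$industrial + both$vehicle, tolerance = 1e-12)
  expect_true(all(both$combined >= 0))

  # superposition: union field equals the sum of single-source fields
  fa <- annual_mean_field(emission_inventory(list(p1)), rose, rec)
  fb <- annual_mean_field(emission_inventory(list(p2)), rose, rec)
  expect_equal(only_ind$industrial, fa$industrial + fb$industrial,
               tolerance = 1e-9)

  # degenerate rose: one cell, weight 1, equals a single steady-state call
  rose1 <- build_wind_rose(met_series(3, 270, "D"))
  f1 <- annual_mean_field(emission_inventory(list(p1)), rose1, rec)
  direct <- point_source_concentration(p1, as.matrix(rec), 3, 270, "D")
  expect_equal(f1$industrial, unname(direct), tolerance = 1e-12)
})

test_that("receptor values grow monotonically with any source's emission", {
  rose <- build_wind_rose(met_series(c(3, 6), c(200, 250), c("C", "D")))
  rec <- expand.grid(x = seq(0, 2000, by = 250), y = seq(0, 2000, by = 250))
  base <- annual_mean_field(emission_inventory(list(
    point_source(1000, 1800, 50, id = "a"),
    point_source(300, 1500, 20, id = "b"))), rose, rec)
  more <- annual_mean_field(emission_inventory(list(
    point_source(1000, 1800, 50, id = "a"),
    point_source(300, 1500, 35, id = "b"))), rose, rec)
  expect_true(all(more$industrial >= base$industrial - 1e-15))
})
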