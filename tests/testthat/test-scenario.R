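inventory_points <- function(scn) {
  Filter(function(s) s$type == "point", scn$inventory$sources)
}

test_that("identical seeds give byte-identical scenarios, different seeds differ", {
  a <- generate_scenario(tiny_config(42))
  b <- generate_scenario(tiny_config(42))
  expect_identical(a, b)
  c <- generate_scenario(tiny_config(43))
  ax <- vapply(inventory_points(a), function(s) s$coords[1, 1], 0)
  cx <- vapply(inventory_points(c), function(s) s$coords[1, 1], 0)
  expect_false(isTRUE(all.equal(ax, cx)))
})

test_that("generated tonnage and population totals conserve the configuration", {
  scn <- generate_scenario(tiny_config(7))
  tons <- vapply(scn$inventory$sources, `[[`, 0, "annual_tons")
  type <- vapply(scn$inventory$sources, `[[`, "", "type")
  expect_equal(sum(tons[type == "point"]), 237.79, tolerance = 1e-9)
  expect_equal(sum(tons[type == "line"]), 929.0, tolerance = 1e-9)
  expect_identical(sum(scn$blocks$counts$total), 5000L)
  cnt <- scn$blocks$counts
  expect_identical(cnt$white + cnt$black + cnt$other_races, cnt$total)
  expect_identical(cnt$child + cnt$elderly + cnt$other_ages, cnt$total)
})

test_that("road emissions are proportional to road length", {
  scn <- generate_scenario(tiny_config(11))
  lines <- Filter(function(s) s$type == "line", scn$inventory$sources)
  lens <- vapply(lines, function(s) polyline_length(s$coords), 0)
  tons <- vapply(lines, `[[`, 0, "annual_tons")
  expect_equal(tons / sum(tons), lens / sum(lens), tolerance = 1e-12)
})

test_that("blocks tile the extent and the land use carries several classes", {
  scn <- generate_scenario(tiny_config(3))
  W <- scn$grid$n_cols * scn$grid$cell_size
  H <- scn$grid$n_rows * scn$grid$cell_size
  for (poly in scn$blocks$polygons) {
    expect_true(all(poly[, 1] >= 0 & poly[, 1] <= W))
    expect_true(all(poly[, 2] >= 0 & poly[, 2] <= H))
  }
  expect_gte(length(unique(as.vector(scn$landuse$values))), 3)
})

test_that("zero total population yields an all-zero but valid block set", {
  scn <- generate_scenario(tiny_config(5, total_population = 0))
  expect_true(all(scn$blocks$counts$total == 0))
  expect_true(all(as.matrix(scn$blocks$counts[-1]) == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(race_mix = c(white = 0.5, black = 0.3, other_races = 0.3)),
               "sum to 1")
  expect_error(scenario_config(extent_km = c(-1, 5)), "positive")
  expect_error(scenario_config(n_blocks = 0), "positive")
  expect_error(scenario_config(age_mix = c(child = 1)), "named")
})

test_that("scenario writers round-trip through the pipeline readers", {
  scn <- generate_scenario(tiny_config(9))
  dir <- withr::local_tempdir()
  write_scenario(scn, dir)
  back <- read_scenario(dir)
  tons0 <- vapply(scn$inventory$sources, `[[`, 0, "annual_tons")
  tons1 <- vapply(back$inventory$sources, `[[`, 0, "annual_tons")
  expect_equal(tons1, tons0, tolerance = 1e-9)
  geom0 <- lapply(scn$inventory$sources, `[[`, "coords")
  geom1 <- lapply(back$inventory$sources, `[[`, "coords")
  for (i in seq_along(geom0))
    expect_equal(unname(geom1[[i]]), unname(geom0[[i]]), tolerance = 1e-9)
  expect_equal(back$met$wind_speed_ms, scn$met$wind_speed_ms, tolerance = 1e-6)
  expect_identical(back$met$stability_class, scn$met$stability_class)
  expect_identical(back$blocks$counts, scn$blocks$counts)
  expect_equal(back$landuse$values, scn$landuse$values)
  expect_equal(unclass(back$grid), unclass(scn$grid), tolerance = 1e-12)
})
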