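g2 <- grid_spec(0, 0, 2, 2, 30)

test_that("relative risk normalizes to a unit mean and is scale invariant", {
  # uniform population and concentration: risk 1 everywhere
  r <- relative_risk(grid_raster(g2, 5), grid_raster(g2, 0.3))
  expect_true(all(r$values == 1))

  # direct evaluation: pop all 1, conc (0,0,0,4) -> mean(pop*C) = 1 -> R = C
  conc <- grid_raster(g2, c(0, 0, 0, 4))
  rr <- relative_risk(grid_raster(g2, 1), conc)
  expect_equal(as.vector(rr$values), c(0, 0, 0, 4))

  # scaling either input by a positive constant leaves R unchanged
  set.seed(5)
  gp <- grid_spec(0, 0, 6, 6, 30)
  pop <- grid_raster(gp, runif(36, 0, 50))
  cc <- grid_raster(gp, runif(36, 0, 2))
  base <- relative_risk(pop, cc)
  scaled <- relative_risk(grid_raster(gp, pop$values * 3.7),
                          grid_raster(gp, cc$values * 0.002))
  expect_equal(scaled$values, base$values, tolerance = 1e-12)
  expect_equal(mean(base$values), 1, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected or zeroed with a warning", {
  expect_error(relative_risk(grid_raster(g2, 1), grid_raster(grid_spec(0, 0, 3, 3, 30), 1)),
               "grids differ")
  expect_error(relative_risk(grid_raster(g2, -1), grid_raster(g2, 1)), "negative")
  expect_warning(z <- relative_risk(grid_raster(g2, 0), grid_raster(g2, 1)),
                 "zero population-weighted exposure")
  expect_true(all(z$values == 0))
})

test_that("per-block normalization gives unit mean within every block", {
  set.seed(9)
  gp <- grid_spec(0, 0, 4, 4, 30)
  pop <- grid_raster(gp, runif(16, 1, 10))
  cc <- grid_raster(gp, runif(16, 0.1, 2))
  unit <- rep(c(1L, 2L), each = 8)
  r <- relative_risk(pop, cc, unit = unit)
  v <- as.vector(r$values)
  expect_equal(mean(v[unit == 1]), 1, tolerance = 1e-9)
  expect_equal(mean(v[unit == 2]), 1, tolerance = 1e-9)
})

test_that("the risk stack produces all 21 surfaces with the contract intact", {
  scn <- generate_scenario(tiny_config(2))
  res <- run_analysis(scn, tiny_params(tiny_config(2)))
  expect_identical(length(res$risk), 21L)
  expect_setequal(names(res$risk),
                  as.vector(outer(c("industrial", "vehicle", "combined"),
                                  c("total", "white", "black", "other_races",
                                    "child", "elderly", "other_ages"),
                                  function(s, g) sprintf("risk_%s_%s", s, g))))
  for (r in res$risk) expect_equal(mean(r$values), 1, tolerance = 1e-9)
  # combined-source risk is not the sum of the separately normalized parts
  comb <- res$risk$risk_combined_total$values
  parts <- res$risk$risk_industrial_total$values + res$risk$risk_vehicle_total$values
  expect_false(isTRUE(all.equal(comb, parts)))
})

test_that("missing layers and identical groups behave as documented", {
  pop <- dasymetric_map(
    census_blocks(list(cbind(c(0, 60, 60, 0), c(0, 0, 60, 60))),
                  data.frame(total = 90L, white = 45L, black = 45L, other_races = 0L,
                             child = 45L, elderly = 45L, other_ages = 0L)),
    grid_raster(g2, 1), class_fractions("1" = 1), g2)
  conc <- list(industrial = grid_raster(g2, c(1, 2, 3, 4)),
               vehicle = grid_raster(g2, c(4, 3, 2, 1)))
  expect_error(risk_stack(pop, conc), "missing concentration layer: combined")
  conc$combined <- grid_raster(g2, c(5, 5, 5, 5))
  # groups with zero population yield all-zero surfaces with a warning
  expect_warning(relative_risk(pop$other_races, conc$industrial),
                 "zero population-weighted")
  stack <- suppressWarnings(risk_stack(pop, conc))
  # white and black have identical counts here -> identical risk surfaces
  expect_identical(stack$risk_industrial_white$values,
                   stack$risk_industrial_black$values)
  expect_true(all(stack$risk_vehicle_other_races$values == 0))
})
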