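test_that("ESRI ASCII grids round-trip through write/read", {
  m <- matrix(c(1.5, 2, NA, 4, 5, 6), nrow = 2, byrow = TRUE)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, path, cell_size = 2.5, xll = 10, yll = -5)
  g <- read_ascii_grid(path)
  expect_equal(g$data, m)
  expect_equal(g$cell_size, 2.5)
  expect_equal(g$xll, 10)
  expect_equal(g$yll, -5)
})

test_that("DEM volume is positive-only differencing times cell area", {
  a <- matrix(5, 10, 10)
  expect_equal(dem_volume(a, a, cell_size = 2), 0)
  # uniform 1 m drop over 100 cells of 2 m x 2 m -> 400 m3
  expect_equal(dem_volume(a, a - 1, cell_size = 2), 400)
  # deposition (new above old) is excluded
  b <- a
  b[1, ] <- 7
  expect_equal(dem_volume(a, b, cell_size = 2), 0)
  # nodata cells are skipped
  a2 <- a
  a2[1, 1] <- NA
  expect_equal(dem_volume(a2, a - 1, cell_size = 2), 396)
  expect_error(dem_volume(a, matrix(5, 9, 10), cell_size = 2),
               "co-registered")
})

test_that("synthetic scene volume matches the analytic prism", {
  # retreat 10 m, cliff length 200 m, height 20 m -> 40,000 m3
  sc <- sim_dem_pair(nx = 100, ny = 100, cell_size = 2, cliff_height = 20,
                     retreat = 10, epoch_years = 7)
  expect_equal(sc$section_length, 200)
  expect_equal(sc$true_volume, 40000)
  expect_equal(dem_volume(sc$dem_old, sc$dem_new, sc$cell_size), 40000)
  # non-cell-aligned retreat: within one boundary-row of discretization
  sc2 <- sim_dem_pair(nx = 100, ny = 100, cell_size = 2, cliff_height = 20,
                      retreat = 9.3)
  err <- abs(dem_volume(sc2$dem_old, sc2$dem_new, sc2$cell_size) -
               sc2$true_volume)
  expect_lte(err, sc2$cell_size * sc2$section_length * sc2$cliff_height)
  # zero retreat -> identical grids
  sc0 <- sim_dem_pair(nx = 50, ny = 20, cell_size = 1, cliff_height = 5,
                      retreat = 0)
  expect_identical(sc0$dem_old, sc0$dem_new)
  expect_equal(dem_volume(sc0$dem_old, sc0$dem_new, 1), 0)
  expect_error(sim_dem_pair(50, 20, 1, 5, retreat = 100), "extent")
})

test_that("transect retreat recovers the generating retreat exactly", {
  sc <- sim_dem_pair(nx = 100, ny = 100, cell_size = 2, cliff_height = 20,
                     retreat = 10, epoch_years = 2)
  r <- transect_retreat(sc, spacing = 25)
  expect_equal(r$median, 10 / 2, tolerance = 1e-9)
  expect_equal(r$q25, r$median)     # straight cliff: all transects equal
  expect_equal(r$q75, r$median)
  expect_equal(r$n_dropped, 0)
  # invariant under transect spacing for straight parallel boundaries
  r2 <- transect_retreat(sc, spacing = 7)
  expect_equal(r2$median, r$median, tolerance = 1e-9)
})

test_that("transect retreat on explicit parallel lines gives 3.7 m/yr", {
  base <- data.frame(x = c(0, 0), y = c(0, 1700))
  lines <- list("2012" = data.frame(x = c(40, 40), y = c(0, 1700)),
                "2019" = data.frame(x = c(65.9, 65.9), y = c(0, 1700)))
  r <- transect_retreat(base, lines, spacing = 50)
  expect_equal(r$median, 25.9 / 7, tolerance = 1e-9)
  expect_equal(unique(round(r$per_transect$rate, 9)), round(3.7, 9))
  # identical boundaries -> zero everywhere
  r0 <- transect_retreat(base, list("2012" = lines[[1]],
                                    "2019" = lines[[1]]))
  expect_equal(r0$median, 0)
})

test_that("nearest intersection is used on a sinuous cliff line", {
  base <- data.frame(x = c(0, 0), y = c(0, 100))
  # a cliff line that doubles back: crossings at x = 20 and x = 50
  zig <- data.frame(x = c(20, 20, 50, 50), y = c(-10, 110, 110, -10))
  lines <- list("0" = data.frame(x = c(10, 10), y = c(0, 100)), "1" = zig)
  r <- transect_retreat(base, lines, spacing = 20)
  expect_equal(r$median, 10, tolerance = 1e-9)  # 20 - 10, nearest crossing
})

test_that("the N-mobilization chain reproduces the budget worked example", {
  avpa <- annual_volume_per_area(223502, 7, 3.7, 1700)
  expect_equal(avpa, 223502 / 7 / (3.7 * 1700), tolerance = 1e-12)
  expect_equal(avpa, 5.076, tolerance = 1e-3)
  b <- n_mobilization(avpa, ice_fraction = 0.82, bulk_density = 1220,
                      total_n_frac = 0.0016, mineral_n_content = 35.3)
  expect_equal(b$total_n_release, 1.78, tolerance = 0.01)
  expect_equal(b$mineral_n_release, 39.4, tolerance = 0.01)
  # unit identity: mineral content = total fraction expressed in mg/kg
  b2 <- n_mobilization(avpa, mineral_n_content = 0.0016 * 1e6)
  expect_equal(b2$mineral_n_release, 1000 * b2$total_n_release,
               tolerance = 1e-9)
  expect_equal(n_mobilization(0)$total_n_release, 0)
  expect_error(n_mobilization(1, ice_fraction = 1))
})

test_that("budget quantities are linear in the eroded volume", {
  b1 <- n_mobilization(2)
  b2 <- n_mobilization(4)
  expect_equal(b2$total_n_release, 2 * b1$total_n_release)
  expect_equal(b2$mineral_n_release, 2 * b1$mineral_n_release)
  expect_equal(annual_volume_per_area(100, 4, 2, 10),
               annual_volume_per_area(100, 2, 2, 10) / 2)
})

test_that("the emission budget reproduces the seasonal-loss arithmetic", {
  e <- emission_budget(548, 100, mineral_n_release = 39.35)
  expect_equal(e$seasonal_loss, 54.8)
  expect_equal(e$emission_factor, 54.8 / 39350 * 100, tolerance = 1e-12)
  expect_equal(round(e$emission_factor, 2), 0.14)
  expect_equal(round(e$fold_below_ipcc), 7)
  expect_error(emission_budget(548, 100, 0))
})
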