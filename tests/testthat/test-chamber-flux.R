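test_that("flux unit conversion matches the hand chain", {
  times <- c(0, 12.5, 25, 37.5, 50)
  s <- chamber_series(times, 0.33 + 0.001 * times, "N2O",
                      chamber_height = 0.15, air_temp = 278,
                      pressure = 101325)
  r <- compute_flux(s)
  expect_equal(r$slope, 0.001, tolerance = 1e-12)
  expect_equal(r$flux, hand_chamber_flux(0.001, 0.15, 278, 101325),
               tolerance = 1e-12)
  expect_equal(r$flux, 265.2659, tolerance = 1e-4)  # frozen from the hand chain
  expect_equal(r$r2, 1)
  expect_equal(r$rmse, 0)
})

test_that("a constant series yields zero flux and passes QC", {
  s <- chamber_series(c(0, 12.5, 25, 37.5, 50), rep(0.33, 5), "N2O",
                      chamber_height = 0.2, air_temp = 280,
                      standard_sd = 0.003)
  r <- compute_flux(s)
  expect_equal(r$slope, 0)
  expect_equal(r$flux, 0)
  expect_equal(r$rmse, 0)
  expect_true(r$qc_pass)
  expect_true(is.na(r$r2))
})

test_that("flux is linear in slope/height/pressure and inverse in temperature", {
  base <- compute_flux(sim_chamber_series(100, 0.15, 278))$flux
  expect_equal(compute_flux(sim_chamber_series(200, 0.15, 278))$flux,
               2 * base, tolerance = 1e-9)
  s <- sim_chamber_series(100, 0.15, 278)
  s2 <- chamber_series(s$times, s$conc, "N2O", 0.30, 278)  # same slope, 2x height
  expect_equal(compute_flux(s2)$flux, 2 * base, tolerance = 1e-9)
  s3 <- chamber_series(s$times, s$conc, "N2O", 0.15, 278, pressure = 2 * 101325)
  expect_equal(compute_flux(s3)$flux, 2 * base, tolerance = 1e-9)
  s4 <- chamber_series(s$times, s$conc, "N2O", 0.15, 2 * 278)
  expect_equal(compute_flux(s4)$flux, base / 2, tolerance = 1e-9)
})

test_that("CH4 and CO2 fluxes use the carbon mass basis and mg scale", {
  times <- c(0, 12.5, 25, 37.5, 50)
  s_ch4 <- chamber_series(times, 2 + 0.001 * times, "CH4", 0.15, 278)
  expect_equal(compute_flux(s_ch4)$flux,
               hand_chamber_flux(0.001, 0.15, 278, 101325,
                                 g_per_mol = 12.011) / 1000,
               tolerance = 1e-12)
  expect_match(compute_flux(s_ch4)$flux_units, "mg C")
})

test_that("RMSE quality rule applies the 3*SD boundary, ties accepted", {
  expect_false(quality_flag(0.010, 0.003))  # 0.010 > 0.009 -> reject
  expect_true(quality_flag(0.009, 0.003))   # boundary tie -> accept
  expect_true(quality_flag(0, 0))
  expect_error(quality_flag(-1, 0.003))
})

test_that("pore-gas gradient flux matches the independent Fick chain", {
  f <- pore_gradient_flux(pore_ppm = 2.4, surface_ppm = 0.33, depth = 0.1,
                          air_filled_porosity = 0.2, total_porosity = 0.5,
                          temp = 278)
  expect_equal(f, hand_pore_flux(2.4, 0.33, 0.1, 0.2, 0.5, 278),
               tolerance = 1e-12)
  expect_gt(f, 0)
  # zero gradient, linearity in the gradient
  expect_equal(pore_gradient_flux(0.33, 0.33, 0.1, 0.2, 0.5, 278), 0)
  f2 <- pore_gradient_flux(0.33 + 2 * (2.4 - 0.33), 0.33, 0.1, 0.2, 0.5, 278)
  expect_equal(f2, 2 * f, tolerance = 1e-12)
  expect_error(pore_gradient_flux(2.4, 0.33, 0, 0.2, 0.5, 278))
  expect_error(pore_gradient_flux(2.4, 0.33, 0.1, 0, 0.5, 278),
               "nonzero gradient")
})

test_that("series validation rejects short or disordered input", {
  expect_error(chamber_series(c(0, 10), c(1, 2), "N2O", 0.15, 278),
               "at least 3")
  expect_error(chamber_series(c(0, 10, 5), c(1, 2, 3), "N2O", 0.15, 278),
               "increasing")
  expect_error(chamber_series(c(0, 10, 20), c(1, 2, 3), "N2O", -1, 278))
})

test_that("compute_flux_table yields one QC'd row per enclosure", {
  times <- c(0, 12.5, 25, 37.5, 50)
  df <- rbind(
    data.frame(plot_id = "p1", surface_class = "yedoma_grass",
               time_min = times, conc_ppm = 0.33 + 0.002 * times,
               height_m = 0.15, temp_C = 5, standard_sd_ppm = 0.003),
    data.frame(plot_id = "p2", surface_class = "bare_sand",
               time_min = times, conc_ppm = rep(0.33, 5),
               height_m = 0.15, temp_C = 5, standard_sd_ppm = 0.003)
  )
  out <- compute_flux_table(df)
  expect_equal(nrow(out), 2)
  expect_true(all(out$qc_pass))
  expect_equal(out$flux[out$plot_id == "p2"], 0)
  expect_gt(out$flux[out$plot_id == "p1"], 0)
})
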