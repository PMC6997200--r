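test_that("relief_spec enforces class-amplitude consistency", {
  expect_equal(relief_spec(1)$relief_amplitude, 35)
  expect_error(relief_spec(1, relief_amplitude = 80), "inconsistent")
  expect_error(relief_spec(3, relief_amplitude = 150), "inconsistent")
})

test_that("make_dem hits the relief target per 10-km block and is deterministic", {
  d1 <- make_dem(c(200, 200), 50, relief_spec(1), seed = 5)
  expect_true(all(topoclimvel:::.block_ranges(d1$values, 50) < 50))
  d3 <- make_dem(c(200, 200), 50, relief_spec(3), seed = 5)
  expect_true(any(topoclimvel:::.block_ranges(d3$values, 50) > 200))
  # block ranges within +/-20% of the specified amplitude
  br <- topoclimvel:::.block_ranges(d3$values, 50)
  expect_true(all(br >= 0.8 * 400 & br <= 1.2 * 400))
  expect_identical(d3$values, make_dem(c(200, 200), 50, relief_spec(3),
                                       seed = 5)$values)
  expect_false(identical(d3$values, make_dem(c(200, 200), 50, relief_spec(3),
                                             seed = 6)$values))
  expect_error(make_dem(c(2, 2), 10000, relief_spec(1), seed = 1), "10 km")
})

test_that("temperature terms act as specified when isolated", {
  # pure lapse: two elevations differing by 100 m -> 0.65 C difference
  dem <- clim_grid(matrix(c(100, 200, 100, 200), 2, 2), 100)
  p <- climate_gen_params(lapse_rate = -0.0065, meridional_gradient = 0,
                          radiation_coeff = 0, cold_pool_coeff = 0,
                          noise_sd = 0, precip_noise_sd = 0)
  n <- make_monthly_climate(dem, p)
  tj <- n$temps[[1]]$values
  expect_equal(tj[1, 1] - tj[2, 1], 0.65, tolerance = 1e-12)

  # everything zeroed on a flat DEM -> spatially constant fields
  flat <- clim_grid(matrix(250, 4, 4), 100)
  p0 <- climate_gen_params(meridional_gradient = 0, radiation_coeff = 0,
                           cold_pool_coeff = 0, noise_sd = 0,
                           precip_noise_sd = 0)
  n0 <- make_monthly_climate(flat, p0)
  for (m in c(1, 7)) expect_equal(stats::sd(n0$temps[[m]]$values), 0)
  expect_equal(stats::sd(n0$precip_annual$values), 0)
})

test_that("cold-air pooling cools a depression most strongly in winter", {
  v <- matrix(200, 21, 21)
  v[11, 11] <- 150                       # a 50-m sink
  dem <- clim_grid(v, 100)
  p <- climate_gen_params(meridional_gradient = 0, radiation_coeff = 0,
                          cold_pool_coeff = 0.02, noise_sd = 0,
                          precip_noise_sd = 0)
  n <- make_monthly_climate(dem, p)
  anom <- function(m) {
    tm <- n$temps[[m]]$values
    lapse_only <- p$sea_level_monthly_T[m] + p$lapse_rate * v
    (tm - lapse_only)[11, 11]
  }
  expect_lt(anom(1), anom(7))            # January anomaly more negative
  expect_equal(anom(7), 0, tolerance = 1e-12)  # no pooling in July
})

test_that("generated lapse with elevation is recovered by regression", {
  dem <- make_dem(c(100, 100), 100, relief_spec(2), seed = 9)
  p <- climate_gen_params(meridional_gradient = 0, radiation_coeff = 0,
                          cold_pool_coeff = 0, noise_sd = 0.05,
                          precip_noise_sd = 0, seed = 10)
  n <- make_monthly_climate(dem, p)
  fit <- stats::lm(as.vector(n$temps[[1]]$values) ~ as.vector(dem$values))
  expect_equal(unname(stats::coef(fit)[2]), p$lapse_rate, tolerance = 0.1)
})

test_that("delta fields have the stated mean, ordering and determinism", {
  target <- toy_grid(100, 100, cell_size = 100)
  flat <- delta_spec("RCP4.5", warming_gradient = 0, perturb_sd = 0, seed = 3)
  d <- make_delta_fields(flat, target)
  expect_true(all(abs(d$t_deltas[[6]]$values - flat$mean_warming) < 1e-12))
  noisy <- delta_spec("RCP4.5", perturb_sd = 0.05, seed = 3)
  dn <- make_delta_fields(noisy, target)
  expect_equal(mean(dn$t_deltas[[1]]$values), noisy$mean_warming,
               tolerance = 0.05)
  # scenario ordering of spatial means
  means <- vapply(default_scenarios(1), function(s)
    mean(make_delta_fields(s, target)$t_deltas[[1]]$values), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_identical(make_delta_fields(noisy, target)$p_delta$values,
                   dn$p_delta$values)
})

test_that("reserve polygons have requested areas, stay disjoint and in-domain", {
  dom <- toy_grid(200, 200, cell_size = 50)
  one <- make_pa_polygons(dom, 1, area_range = c(10, 10), seed = 2)
  expect_equal(unname(pa_areas(one)[1]), 10, tolerance = 0.05)

  pas <- make_pa_polygons(dom, 40, area_range = c(2, 50), seed = 2)
  a <- pa_areas(pas)
  expect_true(all(a >= 2))
  xy_all <- do.call(rbind, lapply(pas, `[[`, "xy"))
  expect_true(all(xy_all[, 1] >= 0 & xy_all[, 1] <= 10000 &
                  xy_all[, 2] >= 0 & xy_all[, 2] <= 10000))
  # pairwise disjoint: no vertex of one polygon inside another
  for (i in seq_along(pas)) for (j in seq_along(pas)) {
    if (i == j) next
    expect_false(any(topoclimvel:::.points_in_polygon(
      pas[[i]]$xy[, 1], pas[[i]]$xy[, 2], pas[[j]]$xy)))
  }
  expect_error(make_pa_polygons(dom, 5000, area_range = c(50, 100), seed = 1,
                                max_tries = 5),
               "non-overlapping")
})

test_that("polygon WKT csv round-trips geometry and ids", {
  dom <- toy_grid(100, 100, cell_size = 50)
  pas <- make_pa_polygons(dom, 5, area_range = c(2, 20), seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pa_csv(pas, path)
  back <- read_pa_csv(path)
  expect_equal(length(back), 5)
  expect_equal(back[[3]]$pa_id, pas[[3]]$pa_id)
  expect_equal(back[[3]]$xy, pas[[3]]$xy, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("relief_class_grid classifies blocks by height range", {
  v <- matrix(0, 20, 40)
  v[, 21:40] <- matrix(rep(seq(0, 300, length.out = 20), each = 20), 20, 20)
  dem <- clim_grid(v, 500)   # two 10-km blocks: flat | rugged
  rc <- relief_class_grid(dem)
  expect_equal(unique(as.vector(rc$values[, 1:20])), 1)
  expect_equal(unique(as.vector(rc$values[, 21:40])), 3)
})
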