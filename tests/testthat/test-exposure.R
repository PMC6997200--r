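square_pa <- function(id, x0, y0, w) {
  list(pa_id = id, xy = rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + w),
                              c(x0, y0 + w), c(x0, y0)))
}

vel_from_matrix <- function(m, cs = 100, years = 89) {
  d <- clim_grid(m * 1000 * years, cs)    # distances giving velocity == m
  velocity_from_distance(d, years)
}

test_that("zonal means, disappeared fractions and covariates are correct", {
  m <- matrix(2, 10, 10)
  vel <- vel_from_matrix(m)
  dem <- clim_grid(matrix(seq(100, 140, length.out = 100), 10, 10), 100)
  pas <- structure(list(square_pa(1, 100, 100, 400),
                        square_pa(2, 600, 600, 350)), class = "pa_set")
  z <- zonal_mean(vel, pas, dem)
  expect_equal(z$mean_velocity_kmyr, c(2, 2))
  expect_equal(z$frac_disappeared, c(0, 0))
  expect_equal(z$area_ha, c(16, 12.25), tolerance = 1e-9)
  expect_true(all(z$relief_region == 1))   # 100-m total relief on one block

  # half-disappeared 4-cell reserve: mean over the finite half only
  d2 <- clim_grid(matrix(89000 * c(1, 3, Inf, Inf), 2, 2), 200)
  vel2 <- velocity_from_distance(d2, 89)
  dem2 <- clim_grid(matrix(50, 2, 2), 200)
  pa <- structure(list(square_pa(1, 0, 0, 400)), class = "pa_set")
  z2 <- zonal_mean(vel2, pa, dem2)
  expect_equal(z2$frac_disappeared, 0.5)
  expect_equal(z2$mean_velocity_kmyr, 2)   # mean of 1 and 3
})

test_that("tiny reserves fall back to intersecting cells on coarse grids", {
  vel <- vel_from_matrix(matrix(1:4, 2, 2), cs = 1000)
  dem <- clim_grid(matrix(10, 20, 20), 100)
  tiny <- structure(list(square_pa(1, 1020, 1020, 150)), class = "pa_set")
  z <- zonal_mean(vel, tiny, dem)            # no 1-km centre inside
  expect_equal(z$n_cells, 1)
  expect_equal(z$mean_velocity_kmyr, vel$velocity$values[1, 2])
})

test_that("top_fraction takes floor(fraction * N) with pa_id tie-breaks", {
  rec <- data.frame(pa_id = 1:100, mean_velocity_kmyr = rev(seq_len(100)))
  expect_equal(sort(top_fraction(rec, 0.05)), 1:5)
  # brute-force count check across N
  for (n in c(1, 19, 20, 21, 199)) {
    r <- data.frame(pa_id = seq_len(n), mean_velocity_kmyr = stats::runif(n))
    expect_equal(length(top_fraction(r, 0.05)), floor(0.05 * n))
  }
  # all equal velocities -> the lowest ids win
  tie <- data.frame(pa_id = 1:40, mean_velocity_kmyr = 1)
  expect_equal(sort(top_fraction(tie, 0.1)), 1:4)
  # fully disappeared reserves never enter the ranking
  rec$mean_velocity_kmyr[1:2] <- NA
  expect_false(any(top_fraction(rec, 0.05) %in% 1:2))
  expect_error(top_fraction(rec[0, ], 0.05), "empty")
})

test_that("hotspot overlap counts and percentages follow set arithmetic", {
  expect_equal(hotspot_overlap(1:10, 1:10)$pct_shared, 100)
  expect_equal(hotspot_overlap(1:10, 11:20)$pct_shared, 0)
  ov <- hotspot_overlap(1:10, 6:15)
  expect_equal(ov$n_shared, 5)
  expect_equal(ov$pct_shared, 50)
  expect_equal(hotspot_overlap(1:10, 6:15, 8:30)$n_shared_triple, 3)
})

test_that("paired test matches the closed form and stats::t.test", {
  fine <- c(1, 3, 0, 2, 1); coarse <- fine + c(2, -1, 3, 0, 1)
  r <- paired_velocity_test(fine, coarse)
  expect_equal(r$t, 1 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-10)
  tt <- stats::t.test(coarse, fine, paired = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  expect_equal(r$prop_coarse_gt_fine, 3 / 5)

  # identical resolutions: zero differences, no strict exceedances
  r0 <- paired_velocity_test(fine, fine)
  expect_true(r0$degenerate)
  expect_equal(r0$prop_coarse_gt_fine, 0)
  # constant nonzero differences: flagged, not crashed
  rc <- paired_velocity_test(fine, fine + 1)
  expect_true(rc$degenerate)
  expect_true(is.na(rc$t))
  expect_equal(rc$mean_diff, 1)
  expect_error(paired_velocity_test(1, 2), "pairs")
})

test_that("relative difference is symmetric-normalised with the coarse sign", {
  expect_equal(relative_difference(2, 2), 0)
  expect_equal(relative_difference(1, 3), 1)
  expect_equal(relative_difference(3, 1), -1)
  expect_warning(rd <- relative_difference(c(0, 1), c(0, 2)), "zero")
  expect_true(is.na(rd[1]))
  expect_equal(rd[2], 2 / 3, tolerance = 1e-12)
  set.seed(2)
  a <- stats::runif(100); b <- stats::runif(100)
  expect_true(all(abs(relative_difference(a, b)) < 2))
})

simulate_rd_records <- function(n, beta_elev = 0.3, beta_relief = 0,
                                sd = 0.2, seed = 1) {
  set.seed(seed)
  relief <- sample(1:3, n, replace = TRUE)
  area <- exp(stats::runif(n, log(2), log(1000)))
  elev <- exp(stats::runif(n, log(5), log(500)))
  scen <- sample(c("RCP2.6", "RCP4.5", "RCP8.5"), n, replace = TRUE)
  rd <- 0.1 + beta_relief * relief + beta_elev * log(elev) +
    stats::rnorm(n, sd = sd)
  data.frame(rel_diff = rd, relief_region = relief, area_ha = area,
             elev_range_m = elev, scenario = scen)
}

test_that("the GLM recovers a known elevation-range coefficient without bias", {
  z <- vapply(1:10, function(s) {
    rec <- simulate_rd_records(500, beta_elev = 0.3, seed = s)
    cf <- glm_relative_diff(rec)$coefficients
    (cf["log_elev_range", "Estimate"] - 0.3) /
      cf["log_elev_range", "Std. Error"]
  }, numeric(1))
  expect_lt(abs(mean(z)), 1)            # unbiased: mean z near 0
  expect_gte(mean(abs(z) < 3), 0.8)     # individual fits within 3 SEs
})

test_that("effect sizes equal coefficient times covariate range (identity link)", {
  rec <- simulate_rd_records(300, beta_elev = 0.25, beta_relief = 0.1,
                             seed = 7)
  fit <- glm_relative_diff(rec)
  cf <- stats::coef(fit$fit)
  es <- fit$effect_sizes
  for (p in c("relief", "log_area", "log_elev_range")) {
    x <- switch(p, relief = as.numeric(rec$relief_region),
                log_area = log(rec$area_ha),
                log_elev_range = log(rec$elev_range_m))
    want <- abs(cf[p] * diff(range(x)))
    expect_equal(es$effect_size[es$predictor == p], unname(want),
                 tolerance = 1e-9)
    expect_equal(es$sign[es$predictor == p], unname(sign(cf[p])))
  }
})

test_that("a null predictor's effect size shrinks with sample size", {
  rec <- simulate_rd_records(2000, beta_elev = 0.3, sd = 0.1, seed = 3)
  fit <- glm_relative_diff(rec)
  es <- fit$effect_sizes
  expect_lt(es$effect_size[es$predictor == "log_area"], 0.02)
  # and is systematically smaller than at low n (averaged over replicates)
  e_small <- mean(vapply(1:5, function(s) {
    f <- glm_relative_diff(simulate_rd_records(60, beta_elev = 0.3, sd = 0.1,
                                               seed = s))
    f$effect_sizes$effect_size[f$effect_sizes$predictor == "log_area"]
  }, numeric(1)))
  e_big <- mean(vapply(1:5, function(s) {
    f <- glm_relative_diff(simulate_rd_records(2000, beta_elev = 0.3,
                                               sd = 0.1, seed = s))
    f$effect_sizes$effect_size[f$effect_sizes$predictor == "log_area"]
  }, numeric(1)))
  expect_lt(e_big, e_small)
})

test_that("a positive relief effect is recovered when coarse-fine grows with relief", {
  rec <- simulate_rd_records(800, beta_elev = 0, beta_relief = 0.15, seed = 9)
  fit <- glm_relative_diff(rec)
  cf <- fit$coefficients
  expect_gt(cf["relief", "Estimate"], 0)
  expect_gt(cf["relief", "t value"], 2)
})

test_that("degenerate GLM inputs are rejected explicitly", {
  rec <- simulate_rd_records(100, seed = 5)
  expect_error(glm_relative_diff(rec[1:10, ]), "30")
  rec$elev_range_m <- 0
  expect_error(glm_relative_diff(rec), "positive")
  rec2 <- simulate_rd_records(100, seed = 6)
  rec2$area_ha <- 10           # constant covariate -> rank deficiency
  expect_error(glm_relative_diff(rec2), "constant|deficien")
})
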