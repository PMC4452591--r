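test_that("maximum reef depth follows the light-attenuation relation", {
  expect_identical(max_reef_depth(450, 0.05, 450), 0)
  expect_equal(max_reef_depth(1800, 0.05, 450), log(4) / 0.05)
  expect_identical(max_reef_depth(300, 0.05, 450), 0)  # sub-threshold light
  expect_true(is.na(max_reef_depth(NA, 0.05, 450)))
  expect_error(max_reef_depth(1800, -0.01, 450), "K490")
  # deeper light penetration with clearer water
  expect_gt(max_reef_depth(1800, 0.03, 450), max_reef_depth(1800, 0.08, 450))
})

test_that("the environmental envelope is inclusive and handles missing data", {
  lim <- default_limits()
  expect_true(check_env_cell(26, 35, 1, 0.1, 3.5, lim))
  expect_true(check_env_cell(lim$T_min, lim$S_max, lim$NO3_max, lim$PO4_max,
                             lim$omega_min, lim))          # bounds inclusive
  expect_false(check_env_cell(lim$T_min - 0.1, 35, 1, 0.1, 3.5, lim))
  expect_false(check_env_cell(26, 35, lim$NO3_max + 0.1, 0.1, 3.5, lim))
  expect_false(check_env_cell(NA, 35, 1, 0.1, 3.5, lim))   # missing -> fail
  # omega below threshold fails, unless unchecked or missing
  expect_false(check_env_cell(26, 35, 1, 0.1, 2.0, lim))
  expect_true(check_env_cell(26, 35, 1, 0.1, 2.0, lim, omega_checked = FALSE))
  expect_true(check_env_cell(26, 35, 1, 0.1, NA, lim))
})

test_that("prediction matches a literal brute-force evaluation", {
  lim <- default_limits()
  for (seed in c(3, 19, 37)) {
    env <- random_tiny_world(seed)
    got <- predict_habitat(env, lim)
    want <- oracle_predict(env, lim)
    expect_identical(got$fine_mask$values, want)
    expect_identical(got$coarse_fraction$values,
                     aggregate_fraction(got$fine_mask,
                                        env$temperature$spec)$values)
  }
})

test_that("prediction honours the omega mask region", {
  # one coarse cell with hopeless omega, rescued by the regional mask
  om <- matrix(3.5, 2, 2); om[1, 1] <- 1.0
  env <- tiny_world(omega = om)
  lim <- default_limits()
  none <- predict_habitat(env, lim)
  expect_identical(sum(none$coarse_fraction$values > 0), 3L)
  mask <- region_mask("box", -1, 0, 0, 1)   # covers the bad cell
  rescued <- predict_habitat(env, lim, mask)
  expect_identical(sum(rescued$coarse_fraction$values > 0), 4L)
  expect_identical(rescued$fine_mask$values,
                   oracle_predict(env, lim, mask))
})

test_that("uniform suitable world with flat shelf is fully habitable", {
  env <- tiny_world(Z = 10)               # Z_max ~ 27.7 m everywhere
  res <- predict_habitat(env, default_limits())
  expect_true(all(res$fine_mask$values))
  expect_true(all(res$coarse_fraction$values == 1))
  # raising I_min until Z_max < 10 m kills every cell
  lim_hi <- default_limits()
  lim_hi$I_min <- 1800 * exp(-0.05 * 9)    # Z_max = 9 m < shelf depth
  res2 <- predict_habitat(env, lim_hi)
  expect_identical(sum(res2$fine_mask$values), 0L)
  expect_identical(res2$total_area_km2, 0)
})

test_that("a failing envelope cell blanks its whole fine block", {
  po4 <- matrix(0.1, 2, 2); po4[2, 1] <- 0.9
  env <- tiny_world(PO4 = po4)
  res <- predict_habitat(env, default_limits())
  expect_identical(res$coarse_fraction$values[2, 1], 0)
  expect_true(all(res$coarse_fraction$values[-2] == 1))
})

test_that("suitability is monotone in I_min and in envelope width", {
  env <- random_tiny_world(23)
  lim <- default_limits()
  masks <- lapply(c(100, 300, 450, 700), function(I) {
    l <- lim; l$I_min <- I
    predict_habitat(env, l)
  })
  for (i in 1:3) {
    # raising I_min never turns an unsuitable cell suitable
    expect_true(all(masks[[i]]$fine_mask$values >= masks[[i + 1]]$fine_mask$values))
    expect_gte(masks[[i]]$total_area_km2, masks[[i + 1]]$total_area_km2)
  }
  wide <- tolerance_limits(lim$T_min - 5, lim$T_max + 5, lim$S_min - 5,
                           lim$S_max + 5, lim$NO3_max * 2, lim$PO4_max * 2,
                           lim$omega_min / 2, lim$I_min)
  expect_true(all(predict_habitat(env, wide)$fine_mask$values >=
                    predict_habitat(env, lim)$fine_mask$values))
})

test_that("area accounting is consistent across both routes", {
  env <- random_tiny_world(37)
  res <- predict_habitat(env, default_limits())
  via_fraction <- sum(res$coarse_fraction$values *
                        cell_areas(res$coarse_fraction$spec))
  expect_lt(abs(res$total_area_km2 / via_fraction - 1), 0.001)
  # a fully suitable 1-degree equatorial block carries the analytic cell area
  env1 <- tiny_world(Z = 10, lat0 = 0)
  res1 <- predict_habitat(env1, default_limits())
  block <- aggregate_fraction(res1$fine_mask, env1$temperature$spec)
  expect_equal(habitat_area(res1),
               sum(cell_areas(env1$temperature$spec) * block$values),
               tolerance = 1e-4)
  expect_equal(cell_area(0, 1, 1), oracle_cell_area(0, 1, 1), tolerance = 1e-9)
})
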