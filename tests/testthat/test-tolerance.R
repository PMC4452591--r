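fine2 <- grid_spec(0, 2, 0, 2, 1 / 120)

test_that("vertex-membership rasterization marks exactly the vertex cells", {
  res <- 1 / 120
  # one vertex strictly inside one cell
  p1 <- data.frame(polygon_id = 1, lat = 0.5 * res + 0.3 * res, lon = 0.5 * res)
  obs1 <- rasterize_reefs(p1, fine2)
  expect_identical(sum(obs1$fine_mask$values), 1L)
  expect_true(obs1$fine_mask$values[1, 1])
  # 4-vertex polygon, one vertex in each of 4 adjacent cells
  ctr <- res  # shared corner of cells (1,1),(1,2),(2,1),(2,2)
  p4 <- data.frame(polygon_id = 1,
                   lat = ctr + c(-0.4, -0.4, 0.4, 0.4) * res,
                   lon = ctr + c(-0.4, 0.4, -0.4, 0.4) * res)
  obs4 <- rasterize_reefs(p4, fine2)
  expect_identical(sum(obs4$fine_mask$values), 4L)
  expect_true(all(obs4$fine_mask$values[1:2, 1:2]))
  # vertex exactly on a shared edge: the half-open convention owns it upward
  pe <- data.frame(polygon_id = 1, lat = res, lon = 0.5 * res)
  obse <- rasterize_reefs(pe, fine2)
  expect_identical(sum(obse$fine_mask$values), 1L)
  expect_true(obse$fine_mask$values[2, 1])
})

test_that("empty and out-of-domain vertices are handled, not fatal", {
  obs0 <- rasterize_reefs(data.frame(polygon_id = integer(),
                                     lat = numeric(), lon = numeric()), fine2)
  expect_identical(sum(obs0$fine_mask$values), 0L)
  pout <- data.frame(polygon_id = 1:2, lat = c(0.5, 30), lon = c(0.5, 0.5))
  expect_message(obs <- rasterize_reefs(pout, fine2), "dropped 1")
  expect_identical(obs$n_dropped, 1L)
  expect_identical(sum(obs$fine_mask$values), 1L)
})

test_that("observed coarse fraction equals the aggregated fine mask", {
  obs <- ref_observations()
  expect_identical(obs$coarse_fraction$values,
                   aggregate_fraction(obs$fine_mask,
                                      obs$coarse_fraction$spec)$values)
})

test_that("a single reef cell pins every limit to that cell's values", {
  env <- tiny_world(temperature = matrix(c(24, 25, 26, 27), 2),
                    salinity = matrix(c(33, 34, 35, 36), 2),
                    NO3 = matrix(c(1, 2, 3, 4), 2) / 2,
                    PO4 = matrix(c(1, 2, 3, 4), 2) / 20,
                    omega = matrix(c(3.1, 3.3, 3.5, 3.7), 2))
  p <- data.frame(polygon_id = 1, lat = -0.5, lon = 0.5)  # coarse cell (1,1)
  obs <- rasterize_reefs(p, env$Z$spec)
  d <- derive_limits(obs, env)
  expect_identical(c(d$T_min, d$T_max), c(24, 24))
  expect_identical(c(d$S_min, d$S_max), c(33, 33))
  expect_identical(d$NO3_max, 0.5)
  expect_identical(d$PO4_max, 0.05)
  expect_identical(d$omega_min, 3.1)
  expect_identical(d$n_reef_cells, 1L)
})

test_that("time-resolved extremes come from the slices, annual from the mean", {
  env <- tiny_world()
  months <- lapply(seq(20, 31), function(Tm)
    raster_grid(env$temperature$spec, matrix(Tm, 2, 2)))
  env$monthly <- list(temperature = months)
  p <- data.frame(polygon_id = 1, lat = 0.5, lon = 0.5)
  obs <- rasterize_reefs(p, env$Z$spec)
  ann <- derive_limits(obs, env, "annual")
  expect_identical(c(ann$T_min, ann$T_max), c(26, 26))
  mon <- derive_limits(obs, env, "monthly")
  expect_identical(c(mon$T_min, mon$T_max), c(20, 31))
})

test_that("annual ranges nest in monthly, monthly in weekly", {
  w <- ref_world()
  obs <- ref_observations()
  ann <- derive_limits(obs, w$env, "annual")
  mon <- derive_limits(obs, w$env, "monthly")
  wk <- derive_limits(obs, w$env, "weekly")
  expect_lte(mon$T_min, ann$T_min); expect_gte(mon$T_max, ann$T_max)
  expect_lte(wk$T_min, mon$T_min); expect_gte(wk$T_max, mon$T_max)
  expect_lte(mon$S_min, ann$S_min); expect_gte(mon$S_max, ann$S_max)
  expect_gte(mon$NO3_max, ann$NO3_max)
  expect_gte(mon$PO4_max, ann$PO4_max)
})

test_that("adding reef cells never narrows derived ranges", {
  env <- random_tiny_world(5)
  res <- 1 / 120
  pts <- data.frame(polygon_id = 1:3,
                    lat = c(-0.6, 0.4, 0.6), lon = c(0.4, 0.6, 1.4))
  obs_small <- rasterize_reefs(pts[1:2, ], env$Z$spec)
  obs_big <- rasterize_reefs(pts, env$Z$spec)
  a <- derive_limits(obs_small, env)
  b <- derive_limits(obs_big, env)
  expect_lte(b$T_min, a$T_min); expect_gte(b$T_max, a$T_max)
  expect_lte(b$S_min, a$S_min); expect_gte(b$S_max, a$S_max)
  expect_gte(b$NO3_max, a$NO3_max); expect_gte(b$PO4_max, a$PO4_max)
})

test_that("self-consistency: derived limits leave only light false negatives", {
  w <- ref_world()
  obs <- ref_observations()
  d <- derive_limits(obs, w$env)
  lim <- as_tolerance_limits(d, I_min = w$truth$I_min)
  res <- predict_habitat(w$env, lim)
  # every reef 1-degree cell passes the envelope; any FN must be light-only
  reef <- obs$coarse_fraction$values > 0
  envok <- reefhab:::coarse_env_ok(w$env, lim)$ok
  expect_true(all(envok[reef]))
})

test_that("an all-missing variable over reef cells is a named error", {
  env <- tiny_world()
  env$NO3$values[] <- NA
  p <- data.frame(polygon_id = 1, lat = 0.5, lon = 0.5)
  obs <- rasterize_reefs(p, env$Z$spec)
  expect_error(derive_limits(obs, env), "NO3")
})
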