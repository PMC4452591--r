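spec10 <- grid_spec(0, 10, 0, 10, 1)

test_that("presence is strictly above zero", {
  f <- matrix(0, 10, 10)
  expect_true(all(presence_matrix(raster_grid(spec10, f))$values == 0))
  f[1, 1] <- 1e-4; f[2, 2] <- 1
  p <- presence_matrix(raster_grid(spec10, f))
  expect_identical(sum(p$values), 2)
  expect_identical(p$values[1, 1], 1)
  expect_error(presence_matrix(raster_grid(spec10, f - 2)), "\\[0, 1\\]")
})

test_that("confusion reproduces hand counts and the signed map", {
  s2 <- grid_spec(0, 2, 0, 2, 1)
  obs <- raster_grid(s2, matrix(c(1, 0, 0, 1), 2))
  pred <- raster_grid(s2, matrix(c(1, 0, 1, 0), 2))
  cc <- confusion(obs, pred)
  expect_identical(c(cc$TP, cc$FP, cc$FN, cc$TN), c(1L, 1L, 1L, 1L))
  expect_identical(cc$signed_map$values, matrix(c(0, 0, -1, 1), 2))
  same <- confusion(obs, obs)
  expect_identical(c(same$FP, same$FN), c(0L, 0L))
  allfp <- confusion(raster_grid(s2, matrix(0, 2, 2)),
                     raster_grid(s2, matrix(1, 2, 2)))
  expect_identical(c(allfp$FP, allfp$TN), c(4L, 0L))
  expect_error(confusion(obs, raster_grid(spec10, matrix(0, 10, 10))),
               "differ")
})

test_that("confusion matches a brute-force tally on random binary pairs", {
  set.seed(99)
  for (i in 1:1000) {
    o <- matrix(rbinom(100, 1, 0.4), 10)
    p <- matrix(rbinom(100, 1, 0.4), 10)
    cc <- confusion(raster_grid(spec10, o), raster_grid(spec10, p))
    want <- oracle_confusion(o, p)
    expect_identical(c(cc$TP, cc$FP, cc$FN, cc$TN),
                     c(want$TP, want$FP, want$FN, want$TN))
    expect_identical(cc$TP + cc$FP + cc$FN + cc$TN, 100L)
  }
})

test_that("rates and the ROC distance behave at the corners", {
  mk <- function(TP, FP, FN, TN)
    structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
              class = "confusion_counts")
  expect_identical(unname(rates(mk(1, 0, 1, 1))["TPR"]), 0.5)
  r <- rates(mk(9, 3, 1, 7))
  expect_identical(unname(r), c(0.9, 0.3))
  perfect <- rates(mk(5, 0, 0, 5))
  expect_identical(unname(roc_distance(perfect["TPR"], perfect["FPR"])), 0)
  expect_equal(unname(roc_distance(0, 1)), sqrt(2))
  expect_error(rates(mk(0, 3, 0, 7)), "undefined")
})

test_that("the sweep recovers the planted optimum within one fine step", {
  w <- ref_world()
  sw <- sweep_imin(w$env, w$truth$limits, ref_observations())
  expect_lte(abs(sw$best_I_min - w$truth$I_min), 10)
  # count conservation at every point
  n_cells <- prod(dim(w$env$temperature$values))
  expect_true(all(rowSums(sw$points[, c("TP", "FP", "FN", "TN")]) == n_cells))
  # FP never increases, FN never decreases along I_min
  expect_true(all(diff(sw$points$FP) <= 0))
  expect_true(all(diff(sw$points$FN) >= 0))
  expect_true(all(diff(sw$points$area_km2) <= 0))
})

test_that("sweep points agree with a direct prediction at the same I_min", {
  w <- ref_world()
  obs <- ref_observations()
  sw <- sweep_imin(w$env, w$truth$limits, obs, grid = c(200, 450),
                   refine_step = NULL)
  for (i in seq_len(nrow(sw$points))) {
    lim <- w$truth$limits
    lim$I_min <- sw$points$I_min[i]
    pred <- predict_habitat(w$env, lim)
    cc <- confusion(presence_matrix(obs$coarse_fraction),
                    presence_matrix(pred$coarse_fraction))
    expect_identical(sw$points$FP[i], cc$FP)
    expect_identical(sw$points$FN[i], cc$FN)
    expect_equal(sw$points$area_km2[i], pred$total_area_km2)
  }
})

test_that("ties in ROC distance resolve to the smallest I_min", {
  # a world whose predictions are identical at every swept value:
  # a uniform 5 m shelf stays suitable far beyond the sweep range
  env <- tiny_world(Z = 5)
  obs_poly <- data.frame(polygon_id = 1:2, lat = c(-0.5, -0.5),
                         lon = c(0.5, 1.5))
  obs <- rasterize_reefs(obs_poly, env$Z$spec)
  sw <- sweep_imin(env, default_limits(), obs, grid = seq(50, 500, 50))
  expect_identical(length(unique(sw$points$distance)), 1L)
  expect_identical(sw$best_I_min, 50)
})

test_that("sweep input validation", {
  env <- tiny_world()
  obs <- rasterize_reefs(data.frame(polygon_id = 1, lat = -0.5, lon = 0.5),
                         env$Z$spec)
  expect_error(sweep_imin(env, default_limits(), obs, grid = numeric()),
               "non-empty")
  expect_error(sweep_imin(env, default_limits(), obs, grid = c(100, 50)),
               "increasing")
})
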