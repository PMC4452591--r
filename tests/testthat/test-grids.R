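test_that("cell_area matches an independent spherical integral", {
  cases <- list(c(0, 1, 1), c(10, 11, 1), c(-40, 40, 0.5), c(39, 40, 1 / 12))
  for (cs in cases)
    expect_equal(cell_area(cs[1], cs[2], cs[3]),
                 oracle_cell_area(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  expect_gt(cell_area(0, 1, 1), 12000)
  expect_lt(cell_area(0, 1, 1), 12500)
})

test_that("cell_area symmetries and degenerate arguments", {
  expect_identical(cell_area(10, 11, 0), 0)
  expect_equal(cell_area(10, 11, 1), cell_area(-11, -10, 1))
  expect_error(cell_area(11, 10, 1), "strictly below")
  expect_error(cell_area(0, 1, -1), "non-negative")
})

test_that("summed cell areas close on the analytic band area", {
  for (res in c(1, 1 / 12, 1 / 120)) {
    spec <- grid_spec(-3, 3, 10, 14, res)
    expect_lt(abs(sum(cell_areas(spec)) / band_area(spec) - 1), 1e-12)
  }
})

test_that("grid_spec rejects inconsistent or out-of-band domains", {
  expect_error(grid_spec(0, 1.5, 0, 2, 1), "integer multiples")
  expect_error(grid_spec(30, 45, 0, 2, 1), "within \\[-40, 40\\]")
  expect_error(grid_spec(2, 1, 0, 2, 1), "lat_min < lat_max")
})

test_that("subdivide yields the canonical block sizes and partitions", {
  s5 <- subdivide(grid_spec(0, 1, 0, 1, 1 / 12), 1 / 120)
  expect_identical(s5$factor^2, 100)
  s1 <- subdivide(grid_spec(0, 1, 0, 1, 1), 1 / 120)
  expect_identical(s1$factor^2, 14400)
  id <- subdivide(grid_spec(0, 2, 0, 2, 1), 1)
  expect_identical(id$factor, 1L)
  expect_identical(id$coarse_row, 1:2)
  # every coarse row index owns exactly `factor` fine rows: a partition
  expect_true(all(table(s1$coarse_row) == s1$factor))
  expect_identical(length(s1$coarse_row), 120L)
  expect_error(subdivide(grid_spec(0, 1, 0, 1, 1 / 12), 1 / 30), "divide")
})

test_that("aggregate_fraction counts, conserves, and is monotone", {
  coarse <- grid_spec(0, 1, 0, 1, 1)
  fine <- grid_spec(0, 1, 0, 1, 1 / 120)
  all_true <- raster_grid(fine, matrix(TRUE, 120, 120))
  expect_identical(aggregate_fraction(all_true, coarse)$values[1, 1], 1)
  all_false <- raster_grid(fine, matrix(FALSE, 120, 120))
  expect_identical(aggregate_fraction(all_false, coarse)$values[1, 1], 0)
  m <- matrix(FALSE, 120, 120); m[seq_len(3600)] <- TRUE
  expect_identical(aggregate_fraction(raster_grid(fine, m), coarse)$values[1, 1],
                   0.25)
  # monotone: adding TRUE cells never decreases any coarse fraction
  set.seed(42)
  for (rep in 1:5) {
    base <- matrix(stats::runif(120 * 120) < 0.3, 120, 120)
    more <- base | (matrix(stats::runif(120 * 120) < 0.2, 120, 120))
    f1 <- aggregate_fraction(raster_grid(fine, base), coarse)$values
    f2 <- aggregate_fraction(raster_grid(fine, more), coarse)$values
    expect_true(all(f2 >= f1))
  }
  expect_error(aggregate_fraction(all_true, grid_spec(0, 1, 0, 2, 1)),
               "do not nest")
})

test_that("lookup_coarse uses the enclosing cell with 1-cell neighbour fill", {
  coarse_spec <- grid_spec(0, 3, 0, 3, 1)
  v <- matrix(as.numeric(1:9), 3, 3)
  fine_spec <- grid_spec(0, 3, 0, 3, 1 / 12)
  lk <- lookup_coarse(fine_spec, raster_grid(coarse_spec, v))
  expect_identical(lk$values[1, 1], v[1, 1])      # inside a valid cell
  expect_identical(lk$values[18, 18], v[2, 2])
  # center missing -> nearest valid neighbour (edge-adjacent preferred)
  v2 <- v; v2[2, 2] <- NA
  lk2 <- lookup_coarse(fine_spec, raster_grid(coarse_spec, v2))
  expect_identical(lk2$values[18, 18], v2[1, 2])  # S neighbour wins the tie
  # isolated missing 3x3 neighbourhood stays missing
  v3 <- matrix(NA_real_, 3, 3)
  lk3 <- lookup_coarse(fine_spec, raster_grid(coarse_spec, v3))
  expect_true(all(is.na(lk3$values)))
})
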