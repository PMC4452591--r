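#' Equal-angle geographic grid specification
#'
#' Defines a regular latitude/longitude grid with cell-centered registration
#' and half-open cells `[lo, hi)` on both axes, so every point maps to exactly
#' one cell. The model works on three nested resolutions: 1 degree
#' (environmental climatologies), 5 arcminutes (irradiance and attenuation)
#' and 30 arcseconds (bathymetry and the habitat mask).
#'
#' @param lat_min,lat_max Latitude bounds in degrees; the band must lie within
#'   40 degrees N to 40 degrees S, the latitude range of the model domain.
#' @param lon_min,lon_max Longitude bounds in degrees, on the `[-180, 180)`
#'   convention.
#' @param resolution Cell size in degrees; the extents must be integer
#'   multiples of it. Canonical values are `1`, `1/12` (5'), `1/120` (30'').
#' @return An object of class `grid_spec` with fields `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max`, `resolution`, `n_lat`, `n_lon`.
#' @examples
#' spec <- grid_spec(-5, 5, 0, 20, 1)
#' spec$n_lat  # 10
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max, resolution) {
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0)
  if (lat_min >= lat_max || lon_min >= lon_max)
    stop("grid bounds must satisfy lat_min < lat_max and lon_min < lon_max")
  if (lat_min < -40 - 1e-9 || lat_max > 40 + 1e-9)
    stop("latitude band must lie within [-40, 40] degrees")
  if (lon_min < -180 - 1e-9 || lon_max > 180 + 1e-9)
    stop("longitude bounds must lie within [-180, 180]")
  n_lat <- (lat_max - lat_min) / resolution
  n_lon <- (lon_max - lon_min) / resolution
  if (abs(n_lat - round(n_lat)) > 1e-6 || abs(n_lon - round(n_lon)) > 1e-6)
    stop("grid extents must be integer multiples of the resolution")
  structure(
    list(lat_min = lat_min, lat_max = lat_max,
         lon_min = lon_min, lon_max = lon_max,
         resolution = resolution,
         n_lat = as.integer(round(n_lat)), n_lon = as.integer(round(n_lon))),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.6g deg, lat [%g, %g], lon [%g, %g]\n",
              x$n_lat, x$n_lon, x$resolution,
              x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return Numeric vector of cell-center latitudes (ascending) or longitudes.
#' @export
lat_centers <- function(spec) {
  spec$lat_min + (seq_len(spec$n_lat) - 0.5) * spec$resolution
}

#' @rdname lat_centers
#' @export
lon_centers <- function(spec) {
  spec$lon_min + (seq_len(spec$n_lon) - 0.5) * spec$resolution
}

same_spec <- function(a, b, tol = 1e-9) {
  abs(a$lat_min - b$lat_min) < tol && abs(a$lat_max - b$lat_max) < tol &&
    abs(a$lon_min - b$lon_min) < tol && abs(a$lon_max - b$lon_max) < tol &&
    abs(a$resolution - b$resolution) < tol
}

#' Gridded raster layer
#'
#' A 2-D field on a [grid_spec()]: rows are latitudes (ascending, row 1 is the
#' southernmost band), columns are longitudes (ascending). Missing data are
#' `NA`; missing cells carry no numeric meaning.
#'
#' @param spec A [grid_spec()].
#' @param values Matrix of dimension `n_lat x n_lon` (a scalar is recycled).
#' @return An object of class `reef_raster` with fields `spec` and `values`.
#' @export
raster_grid <- function(spec, values) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(values, spec$n_lat, spec$n_lon)
  if (!is.matrix(values) || nrow(values) != spec$n_lat || ncol(values) != spec$n_lon)
    stop(sprintf("values must be a %d x %d matrix", spec$n_lat, spec$n_lon))
  structure(list(spec = spec, values = values), class = "reef_raster")
}

#' @export
print.reef_raster <- function(x, ...) {
  cat("reef_raster on ")
  print(x$spec)
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], %d missing of %d\n",
                min(v), max(v), sum(is.na(x$values)), length(x$values)))
  else cat("  all missing\n")
  invisible(x)
}

#' Spherical area of a latitude-longitude cell
#'
#' Exact area of the zone slice bounded by two parallels and `dlon` degrees of
#' longitude on a sphere of radius 6371 km:
#' `R^2 * dlon_rad * (sin(lat_hi) - sin(lat_lo))`.
#'
#' @param lat_lo,lat_hi Latitude bounds in degrees, `lat_lo < lat_hi`.
#' @param dlon Longitudinal width in degrees (>= 0).
#' @return Area in km^2. Vectorized over all arguments.
#' @examples
#' cell_area(0, 1, 1)    # ~12364 km^2, an equatorial 1-degree cell
#' cell_area(10, 11, 1) == cell_area(-11, -10, 1)  # hemispheric symmetry
#' @export
cell_area <- function(lat_lo, lat_hi, dlon) {
  if (any(lat_lo >= lat_hi)) stop("lat_lo must be strictly below lat_hi")
  if (any(lat_lo < -90) || any(lat_hi > 90)) stop("latitudes must lie in [-90, 90]")
  if (any(dlon < 0)) stop("dlon must be non-negative")
  R <- 6371.0
  R^2 * (dlon * pi / 180) * (sinpi(lat_hi / 180) - sinpi(lat_lo / 180))
}

#' Per-cell spherical areas of a grid
#'
#' @param spec A [grid_spec()].
#' @return Matrix (`n_lat x n_lon`) of cell areas in km^2; constant along rows.
#' @export
cell_areas <- function(spec) {
  lo <- spec$lat_min + (seq_len(spec$n_lat) - 1) * spec$resolution
  band <- cell_area(lo, lo + spec$resolution, spec$resolution)
  matrix(band, spec$n_lat, spec$n_lon)
}

#' Analytic area of a grid's full latitude band
#'
#' @param spec A [grid_spec()].
#' @return `R^2 * total_dlon * (sin(lat_max) - sin(lat_min))` in km^2; the sum
#'   of [cell_areas()] closes on this to near machine precision.
#' @export
band_area <- function(spec) {
  cell_area(spec$lat_min, spec$lat_max, spec$lon_max - spec$lon_min)
}

#' Subdivision map between nested resolutions
#'
#' Maps each coarse cell to its block of fine cells. The fine resolution must
#' divide the coarse resolution exactly: a 5' cell subdivides into 100 cells
#' of 30'', a 1-degree cell into 14400.
#'
#' @param coarse A [grid_spec()].
#' @param fine_resolution Fine cell size in degrees.
#' @return List with `factor` (fine cells per coarse cell along one axis),
#'   `fine` (the fine [grid_spec()]), and `coarse_row`, `coarse_col` (integer
#'   vectors giving, for every fine row/column index, the enclosing coarse
#'   row/column). Blocks partition the domain with no overlap or gap.
#' @examples
#' subdivide(grid_spec(0, 1, 0, 1, 1/12), 1/120)$factor^2  # 100
#' @export
subdivide <- function(coarse, fine_resolution) {
  stopifnot(inherits(coarse, "grid_spec"))
  ratio <- coarse$resolution / fine_resolution
  if (abs(ratio - round(ratio)) > 1e-6 || ratio < 1 - 1e-9)
    stop("fine resolution must divide the coarse resolution exactly")
  f <- as.integer(round(ratio))
  fine <- grid_spec(coarse$lat_min, coarse$lat_max,
                    coarse$lon_min, coarse$lon_max, fine_resolution)
  list(factor = f, fine = fine,
       coarse_row = rep(seq_len(coarse$n_lat), each = f),
       coarse_col = rep(seq_len(coarse$n_lon), each = f))
}

check_nesting <- function(fine_spec, coarse_spec) {
  ok <- abs(fine_spec$lat_min - coarse_spec$lat_min) < 1e-9 &&
    abs(fine_spec$lat_max - coarse_spec$lat_max) < 1e-9 &&
    abs(fine_spec$lon_min - coarse_spec$lon_min) < 1e-9 &&
    abs(fine_spec$lon_max - coarse_spec$lon_max) < 1e-9
  ratio <- coarse_spec$resolution / fine_spec$resolution
  if (!ok || abs(ratio - round(ratio)) > 1e-6 || ratio < 1 - 1e-9)
    stop("grids do not nest: bounds must match and resolutions divide exactly")
  as.integer(round(ratio))
}

block_sum <- function(m, f) {
  # sum f x f blocks of a matrix; rowsum on each axis
  g_r <- rep(seq_len(nrow(m) / f), each = f)
  g_c <- rep(seq_len(ncol(m) / f), each = f)
  out <- t(rowsum(t(rowsum(m, g_r, reorder = FALSE)), g_c, reorder = FALSE))
  dimnames(out) <- NULL
  out
}

expand_matrix <- function(m, f) {
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f), drop = FALSE]
}

#' Aggregate a fine boolean mask to coarse-cell fractions
#'
#' For each coarse cell, the fraction of fine cells in its block that are
#' `TRUE`. The denominator is the full block, land and ocean alike, matching
#' the percentage-of-positively-evaluated-cells convention used both for
#' predicted habitat and for observed reefs.
#'
#' @param fine A logical `reef_raster` (NA is treated as `FALSE`).
#' @param coarse A [grid_spec()] in which `fine` nests exactly.
#' @return A `reef_raster` on `coarse` with values in `[0, 1]`.
#' @export
aggregate_fraction <- function(fine, coarse) {
  stopifnot(inherits(fine, "reef_raster"), inherits(coarse, "grid_spec"))
  f <- check_nesting(fine$spec, coarse)
  v <- fine$values
  v[is.na(v)] <- FALSE
  storage.mode(v) <- "double"
  raster_grid(coarse, block_sum(v, f) / f^2)
}

fill_missing_nearest <- function(m) {
  # replace NA cells by the nearest non-missing value within a 1-cell radius;
  # edge-adjacent neighbours (distance 1) take precedence over diagonals,
  # ties broken in fixed order: S, N, W, E, then SW, SE, NW, NE
  if (!anyNA(m)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  filled <- m
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    idx <- is.na(filled)
    if (!any(idx)) break
    cand <- shift(d[1], d[2])
    filled[idx] <- cand[idx]
  }
  filled
}

#' Look up the enclosing coarse value for fine cells
#'
#' Returns, at fine resolution, the value of the enclosing coarse cell. Where
#' that coarse cell is missing, the nearest non-missing coarse neighbour
#' within a 1-cell radius is used (edge-adjacent before diagonal); missing
#' beyond that radius stays missing.
#'
#' @param fine_spec The fine [grid_spec()].
#' @param coarse A `reef_raster` at coarse resolution in which `fine_spec`
#'   nests exactly.
#' @param fill Logical; apply the 1-cell nearest-neighbour fill (default
#'   `TRUE`).
#' @return A `reef_raster` on `fine_spec`.
#' @export
lookup_coarse <- function(fine_spec, coarse, fill = TRUE) {
  stopifnot(inherits(fine_spec, "grid_spec"), inherits(coarse, "reef_raster"))
  f <- check_nesting(fine_spec, coarse$spec)
  v <- if (fill) fill_missing_nearest(coarse$values) else coarse$values
  raster_grid(fine_spec, expand_matrix(v, f))
}
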