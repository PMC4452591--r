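#' Write a raster to netCDF
#'
#' CF-style layout: `lat` and `lon` coordinate variables, both ascending,
#' double precision, missing data via `_FillValue`.
#'
#' @param raster A `reef_raster` (logical values are written as 0/1).
#' @param path Output file path.
#' @param varname Variable name in the file.
#' @param units Units attribute string.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, varname = "field", units = "") {
  stopifnot(inherits(raster, "reef_raster"))
  spec <- raster$spec
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", lat_centers(spec))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", lon_centers(spec))
  v <- ncdf4::ncvar_def(varname, units, list(dlon, dlat),
                        missval = -9.96921e36, prec = "double")
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc))
  vals <- raster$values
  storage.mode(vals) <- "double"
  ncdf4::ncvar_put(nc, v, t(vals))   # file layout is (lon, lat)
  invisible(path)
}

#' Write a list of rasters as one netCDF variable with a time dimension
#'
#' @param rasters List of `reef_raster` layers on a common grid.
#' @param path,varname,units As in [write_raster()].
#' @return `path`, invisibly.
#' @export
write_raster_stack <- function(rasters, path, varname = "field", units = "") {
  stopifnot(length(rasters) > 0)
  spec <- rasters[[1]]$spec
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", lat_centers(spec))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", lon_centers(spec))
  dt <- ncdf4::ncdim_def("time", "index", seq_along(rasters))
  v <- ncdf4::ncvar_def(varname, units, list(dlon, dlat, dt),
                        missval = -9.96921e36, prec = "double")
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc))
  arr <- vapply(rasters, function(r) t(r$values),
                matrix(0, spec$n_lon, spec$n_lat))
  ncdf4::ncvar_put(nc, v, arr)
  invisible(path)
}

find_coord <- function(nc, candidates, path) {
  nm <- intersect(candidates, names(nc$dim))
  if (!length(nm))
    stop(sprintf("malformed netCDF '%s': no %s coordinate (looked for %s)",
                 path, candidates[1], paste(candidates, collapse = ", ")))
  nc$dim[[nm[1]]]
}

#' Read a raster from netCDF
#'
#' Accepts `lat`/`latitude` and `lon`/`longitude` coordinate names, enforces
#' ascending axes (flipping as needed), normalizes longitudes on `[0, 360)`
#' to `[-180, 180)` by rotating columns, and maps `_FillValue` to missing.
#' Longitude cell edges are snapped to the cell-centered registration implied
#' by the coordinate spacing.
#'
#' @param path netCDF file path.
#' @param varname Variable to read; default: the first non-coordinate
#'   variable.
#' @param expected_units If given, a warning is issued when the file's units
#'   attribute does not match.
#' @return A `reef_raster`.
#' @export
read_raster <- function(path, varname = NULL, expected_units = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat_d <- find_coord(nc, c("lat", "latitude"), path)
  lon_d <- find_coord(nc, c("lon", "longitude"), path)
  if (is.null(varname)) varname <- names(nc$var)[1]
  if (!varname %in% names(nc$var))
    stop(sprintf("malformed netCDF '%s': no variable '%s'", path, varname))
  if (!is.null(expected_units)) {
    u <- nc$var[[varname]]$units
    if (!identical(u, expected_units))
      warning(sprintf("'%s': units '%s' do not match expected '%s'",
                      path, u, expected_units))
  }
  vals <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  lat <- lat_d$vals; lon <- lon_d$vals
  # ncvar_get returns dims in file order (lon, lat); transpose to (lat, lon)
  if (length(dim(vals)) != 2)
    stop(sprintf("malformed netCDF '%s': variable '%s' is not 2-D", path, varname))
  m <- t(vals)
  if (lat[1] > lat[length(lat)]) { lat <- rev(lat); m <- m[rev(seq_len(nrow(m))), , drop = FALSE] }
  if (length(lon) > 1 && lon[1] > lon[2]) { lon <- rev(lon); m <- m[, rev(seq_len(ncol(m))), drop = FALSE] }
  # normalize [0, 360) style longitudes to [-180, 180)
  if (any(lon >= 180)) {
    lon2 <- ifelse(lon >= 180, lon - 360, lon)
    ord <- order(lon2)
    lon <- lon2[ord]
    m <- m[, ord, drop = FALSE]
  }
  if (length(lat) < 2 && length(lon) < 2)
    stop(sprintf("malformed netCDF '%s': cannot infer resolution from a single cell",
                 path))
  res_lat <- if (length(lat) > 1) diff(lat[1:2]) else diff(lon[1:2])
  res_lon <- if (length(lon) > 1) diff(lon[1:2]) else res_lat
  if (abs(res_lat - res_lon) > 1e-6)
    stop(sprintf("malformed netCDF '%s': anisotropic resolution", path))
  spec <- grid_spec(lat[1] - res_lat / 2, lat[length(lat)] + res_lat / 2,
                    lon[1] - res_lon / 2, lon[length(lon)] + res_lon / 2,
                    res_lat)
  raster_grid(spec, m)
}

#' Write and read flat key-value configuration files
#'
#' A minimal TOML-style dialect: one `key = value` pair per line, `#`
#' comments, numbers parsed as numeric, everything else kept as strings.
#' Used for tolerance limits, region masks and truth records.
#'
#' @param x Named list (or `tolerance_limits`) to write.
#' @param path File path.
#' @return For [write_config()], `path` invisibly; for [read_config()], a
#'   named list.
#' @export
write_config <- function(x, path) {
  keys <- names(x)
  vals <- vapply(x, function(v)
    if (is.numeric(v)) format(v, digits = 17) else as.character(v), "")
  writeLines(sprintf("%s = %s", keys, vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop(sprintf("malformed config '%s': line '%s'",
                             path, lines[bad][1]))
  keys <- trimws(vapply(kv, `[`, "", 2))
  vals <- trimws(vapply(kv, `[`, "", 3))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(out, keys)
}

#' Read/write tolerance limits as a config file
#'
#' @param limits A [tolerance_limits()].
#' @param path File path.
#' @return The path (write) or a [tolerance_limits()] (read).
#' @export
write_limits <- function(limits, path) {
  stopifnot(inherits(limits, "tolerance_limits"))
  write_config(unclass(limits), path)
}

#' @rdname write_limits
#' @export
read_limits <- function(path) {
  cfg <- read_config(path)
  do.call(tolerance_limits, cfg[c("T_min", "T_max", "S_min", "S_max",
                                  "NO3_max", "PO4_max", "omega_min", "I_min")])
}

#' Write a synthetic world to disk
#'
#' One netCDF per raster layer (time-resolved layers get a time dimension),
#' a CSV of reef-polygon vertices, and a truth config with the planted
#' limits, `I_min`, seed and habitat area. Round-trips losslessly through
#' [read_fixture()] (the truth masks are not serialized; they are
#' recomputable from the layers).
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  e <- world$env
  p <- function(f) file.path(dir, f)
  write_raster(e$temperature, p("temperature.nc"), "temperature", "degC")
  write_raster(e$salinity, p("salinity.nc"), "salinity", "psu")
  write_raster(e$NO3, p("NO3.nc"), "NO3", "umol L-1")
  write_raster(e$PO4, p("PO4.nc"), "PO4", "umol L-1")
  write_raster(e$TA, p("TA.nc"), "TA", "umol kg-1")
  write_raster(e$DIC, p("DIC.nc"), "DIC", "umol kg-1")
  write_raster(e$omega, p("omega.nc"), "omega_ara", "1")
  write_raster(e$PAR, p("PAR.nc"), "PAR", "umol photons m-2 s-1")
  write_raster(e$K490, p("K490.nc"), "K490", "m-1")
  write_raster(e$Z, p("Z.nc"), "Z", "m")
  for (nm in names(e$monthly))
    write_raster_stack(e$monthly[[nm]], p(sprintf("%s_monthly.nc", nm)), nm)
  write_raster_stack(e$weekly_T, p("temperature_weekly.nc"), "temperature")
  utils::write.csv(world$reefs, p("reefs.csv"), row.names = FALSE)
  tl <- world$truth$limits
  write_config(c(unclass(tl),
                 list(seed = world$config$seed,
                      total_area_km2 = world$truth$total_area_km2)),
               p("truth.toml"))
  invisible(dir)
}

read_stack <- function(path, varname) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  vals <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  lat <- nc$dim$lat$vals; lon <- nc$dim$lon$vals
  res <- diff(lat[1:2])
  spec <- grid_spec(lat[1] - res / 2, lat[length(lat)] + res / 2,
                    lon[1] - res / 2, lon[length(lon)] + res / 2, res)
  lapply(seq_len(dim(vals)[3]), function(i)
    raster_grid(spec, t(vals[, , i])))
}

#' Read a synthetic-world fixture directory
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `env` (an [env_stack()]), `reefs` (data frame), and
#'   `truth_limits` (a [tolerance_limits()]).
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  monthly <- list()
  for (nm in c("temperature", "salinity", "NO3", "PO4")) {
    f <- p(sprintf("%s_monthly.nc", nm))
    if (file.exists(f)) monthly[[nm]] <- read_stack(f, nm)
  }
  weekly_T <- if (file.exists(p("temperature_weekly.nc")))
    read_stack(p("temperature_weekly.nc"), "temperature") else NULL
  env <- env_stack(
    temperature = read_raster(p("temperature.nc")),
    salinity = read_raster(p("salinity.nc")),
    NO3 = read_raster(p("NO3.nc")), PO4 = read_raster(p("PO4.nc")),
    PAR = read_raster(p("PAR.nc")), K490 = read_raster(p("K490.nc")),
    Z = read_raster(p("Z.nc")),
    omega = if (file.exists(p("omega.nc"))) read_raster(p("omega.nc")) else NULL,
    TA = if (file.exists(p("TA.nc"))) read_raster(p("TA.nc")) else NULL,
    DIC = if (file.exists(p("DIC.nc"))) read_raster(p("DIC.nc")) else NULL,
    monthly = if (length(monthly)) monthly else NULL,
    weekly_T = weekly_T)
  list(env = env,
       reefs = utils::read.csv(p("reefs.csv")),
       truth_limits = if (file.exists(p("truth.toml")))
         read_limits(p("truth.toml")) else NULL)
}

#' Run the full diagnostic pipeline
#'
#' Wires the stages end to end: (optional) saturation-state computation from
#' TA/DIC, (optional) inverse-mode limit derivation from observed reefs,
#' habitat prediction, and evaluation against observations - either at a
#' fixed `I_min` or with the ROC sweep. Outputs (habitat-fraction map,
#' signed FP/FN map, sweep table, run report) are written under `out_dir`
#' when given. Deterministic for fixed inputs.
#'
#' @param env An [env_stack()] or a fixture directory path.
#' @param reefs Observed reef polygons (data frame or CSV path), or `NULL`
#'   to skip evaluation.
#' @param limits A [tolerance_limits()], a limits config path, or `"derive"`
#'   to run inverse mode (requires `reefs`).
#' @param I_min Fixed minimum light intensity; `NULL` runs [sweep_imin()]
#'   (requires `reefs`).
#' @param omega_mask Optional [region_mask()].
#' @param out_dir Optional output directory.
#' @return A report list: `limits` (every limit actually applied),
#'   `I_min`, `counts` (confusion counts, if evaluated), `rates`,
#'   `total_area_km2`, `rejections`, `best_I_min` and `sweep` (if swept).
#' @export
run_pipeline <- function(env, reefs = NULL, limits = "derive", I_min = NULL,
                         omega_mask = NULL, out_dir = NULL) {
  if (is.character(env)) env <- read_fixture(env)$env
  stopifnot(inherits(env, "env_stack"))
  if (is.character(reefs) && length(reefs) == 1) reefs <- utils::read.csv(reefs)

  if (is.null(env$omega) && !is.null(env$TA) && !is.null(env$DIC))
    env$omega <- omega_field(env$TA, env$DIC, env$temperature, env$salinity)

  obs <- NULL
  if (!is.null(reefs)) obs <- rasterize_reefs(reefs, env$Z$spec)

  if (is.character(limits) && identical(limits, "derive")) {
    if (is.null(obs)) stop("limit derivation requires observed reefs")
    derived <- derive_limits(obs, env, omega_mask = omega_mask)
    limits <- as_tolerance_limits(derived, I_min = if (is.null(I_min)) 450 else I_min)
  } else if (is.character(limits)) {
    limits <- read_limits(limits)
  }
  stopifnot(inherits(limits, "tolerance_limits"))

  sweep <- NULL
  if (is.null(I_min)) {
    if (is.null(obs)) stop("the I_min sweep requires observed reefs")
    sweep <- sweep_imin(env, limits, obs, omega_mask = omega_mask)
    I_min <- sweep$best_I_min
  }
  limits$I_min <- I_min
  pred <- predict_habitat(env, limits, omega_mask)

  counts <- NULL; rr <- NULL
  if (!is.null(obs)) {
    counts <- confusion(presence_matrix(obs$coarse_fraction),
                        presence_matrix(pred$coarse_fraction))
    rr <- rates(counts)
  }
  report <- list(limits = unclass(limits), I_min = I_min,
                 counts = if (!is.null(counts))
                   c(TP = counts$TP, FP = counts$FP,
                     FN = counts$FN, TN = counts$TN),
                 rates = rr,
                 total_area_km2 = pred$total_area_km2,
                 rejections = pred$rejections,
                 best_I_min = if (!is.null(sweep)) sweep$best_I_min,
                 sweep = if (!is.null(sweep)) sweep$points)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_raster(pred$coarse_fraction, file.path(out_dir, "habitat_fraction.nc"),
                 "habitat_fraction", "1")
    if (!is.null(counts))
      write_raster(counts$signed_map, file.path(out_dir, "fp_fn_map.nc"),
                   "observed_minus_predicted", "1")
    if (!is.null(sweep))
      utils::write.csv(sweep$points, file.path(out_dir, "sweep.csv"),
                       row.names = FALSE)
    rpt <- c(report$limits,
             list(total_area_km2 = report$total_area_km2),
             as.list(report$counts), as.list(report$rates),
             as.list(report$rejections))
    write_config(rpt, file.path(out_dir, "report.toml"))
  }
  report
}
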