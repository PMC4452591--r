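#' Rasterize observed reef polygons onto the fine grid
#'
#' Vertex-membership rasterization: every 30-arcsecond cell containing at
#' least one polygon vertex is marked as observed reef habitat (polygon
#' interiors are not filled; observed reef areas are recorded as vertex
#' polygons and the vertex convention preserves the charted extent).
#' Cell membership follows the half-open `[lo, hi)` convention, so a vertex
#' on a shared edge belongs to exactly one cell. Vertices outside the grid
#' are dropped and counted.
#'
#' @param polygons Data frame with columns `polygon_id`, `lat`, `lon`
#'   (degrees).
#' @param spec The fine [grid_spec()] (30 arcseconds).
#' @return An object of class `reef_observations`: `polygons`, `fine_mask`
#'   (logical `reef_raster` on `spec`), `coarse_fraction` (its
#'   [aggregate_fraction()] on the enclosing 1-degree grid), `n_dropped`.
#' @export
rasterize_reefs <- function(polygons, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!all(c("polygon_id", "lat", "lon") %in% names(polygons)))
    stop("polygons must have columns polygon_id, lat, lon")
  mask <- matrix(FALSE, spec$n_lat, spec$n_lon)
  n_dropped <- 0L
  if (nrow(polygons)) {
    rows <- floor((polygons$lat - spec$lat_min) / spec$resolution) + 1
    cols <- floor((polygons$lon - spec$lon_min) / spec$resolution) + 1
    inside <- rows >= 1 & rows <= spec$n_lat & cols >= 1 & cols <= spec$n_lon
    n_dropped <- sum(!inside)
    if (n_dropped)
      message(sprintf("rasterize_reefs: dropped %d out-of-domain vertices",
                      n_dropped))
    mask[cbind(rows[inside], cols[inside])] <- TRUE
  }
  fine_mask <- raster_grid(spec, mask)
  coarse <- grid_spec(spec$lat_min, spec$lat_max, spec$lon_min, spec$lon_max, 1)
  structure(list(polygons = polygons, fine_mask = fine_mask,
                 coarse_fraction = aggregate_fraction(fine_mask, coarse),
                 n_dropped = n_dropped),
            class = "reef_observations")
}

#' @export
print.reef_observations <- function(x, ...) {
  cat(sprintf(
    "reef_observations: %d vertices, %d marked 30'' cells, %d occupied 1-deg cells\n",
    nrow(x$polygons), sum(x$fine_mask$values),
    sum(x$coarse_fraction$values > 0)))
  invisible(x)
}

# extremes of a variable over reef cells, across optional time slices
range_over_reefs <- function(annual, slices, reef, what, trim = 0) {
  vals <- annual$values[reef]
  if (!is.null(slices))
    vals <- c(vals, unlist(lapply(slices, function(r) r$values[reef])))
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop(sprintf("derive_limits: variable '%s' is missing at every reef cell",
                 what))
  if (trim > 0)
    vals <- vals[vals >= stats::quantile(vals, trim) &
                   vals <= stats::quantile(vals, 1 - trim)]
  c(min(vals), max(vals))
}

#' Derive tolerance limits from observed reef locations (inverse mode)
#'
#' Takes the global extremes of each environmental variable over the
#' 1-degree cells where reefs are observed (cells with observed fraction
#' above 0): a two-sided range for temperature and salinity, an upper
#' threshold for nitrate and phosphate, and a lower threshold for omega_ara
#' (restricted to reef cells where omega is available and outside
#' `omega_mask`). With `time_scale = "monthly"` or `"weekly"`, the extremes
#' are taken across all time slices available in the stack (weekly series
#' exist for temperature only; other variables fall back to monthly, then
#' annual). Raw extremes are used - no outlier trimming by default - so
#' single extreme reef locations (e.g. upwelling regions) set the
#' thresholds, as the inverse mode intends. The minimum light intensity is
#' not derived here: depth/reef inconsistencies in charted data make direct
#' inversion unrealistically low, so `I_min` is obtained by the ROC sweep
#' ([sweep_imin()]).
#'
#' @param obs A [rasterize_reefs()] result.
#' @param env An [env_stack()] on the same geographic bounds.
#' @param time_scale One of `"annual"`, `"monthly"`, `"weekly"`.
#' @param omega_mask Optional [region_mask()] excluded from the omega
#'   extreme.
#' @param trim Optional symmetric quantile trim (default 0 = raw extremes);
#'   for sensitivity analysis only.
#' @return An object of class `derived_limits` with fields `T_min`, `T_max`,
#'   `S_min`, `S_max`, `NO3_max`, `PO4_max`, `omega_min`, `time_scale`,
#'   `n_reef_cells`.
#' @export
derive_limits <- function(obs, env, time_scale = c("annual", "monthly", "weekly"),
                          omega_mask = NULL, trim = 0) {
  stopifnot(inherits(obs, "reef_observations"), inherits(env, "env_stack"))
  time_scale <- match.arg(time_scale)
  spec <- env$temperature$spec
  if (!same_spec(obs$coarse_fraction$spec, spec))
    stop("observations and environment are on different 1-degree grids")
  reef <- obs$coarse_fraction$values > 0
  if (!any(reef)) stop("reef mask is empty: no cells to derive limits from")

  slices_for <- function(var) {
    if (time_scale == "annual") return(NULL)
    if (var == "temperature" && time_scale == "weekly" && !is.null(env$weekly_T))
      return(env$weekly_T)
    env$monthly[[var]]
  }
  tr <- range_over_reefs(env$temperature, slices_for("temperature"), reef,
                         "temperature", trim)
  sr <- range_over_reefs(env$salinity, slices_for("salinity"), reef,
                         "salinity", trim)
  nr <- range_over_reefs(env$NO3, slices_for("NO3"), reef, "NO3", trim)
  pr <- range_over_reefs(env$PO4, slices_for("PO4"), reef, "PO4", trim)

  omega_min <- NA_real_
  if (!is.null(env$omega)) {
    usable <- reef & !is.na(env$omega$values) & !mask_matrix(omega_mask, spec)
    if (any(usable)) omega_min <- min(env$omega$values[usable])
  }
  structure(list(T_min = tr[1], T_max = tr[2], S_min = sr[1], S_max = sr[2],
                 NO3_max = nr[2], PO4_max = pr[2], omega_min = omega_min,
                 time_scale = time_scale, n_reef_cells = sum(reef)),
            class = "derived_limits")
}

#' @export
print.derived_limits <- function(x, ...) {
  cat(sprintf(paste0(
    "derived_limits (%s, %d reef cells):\n  T [%g, %g] degC  S [%g, %g] psu\n",
    "  NO3 <= %g  PO4 <= %g  omega_ara >= %s\n"),
    x$time_scale, x$n_reef_cells, x$T_min, x$T_max, x$S_min, x$S_max,
    x$NO3_max, x$PO4_max,
    if (is.na(x$omega_min)) "(not derived)" else format(x$omega_min)))
  invisible(x)
}

#' Combine derived limits with a minimum light intensity
#'
#' @param derived A [derive_limits()] result.
#' @param I_min Minimum light intensity, umol photons m^-2 s^-1 (from
#'   [sweep_imin()] or fixed).
#' @param omega_min Replacement omega threshold if none could be derived.
#' @return A [tolerance_limits()] object.
#' @export
as_tolerance_limits <- function(derived, I_min, omega_min = NULL) {
  stopifnot(inherits(derived, "derived_limits"))
  om <- if (!is.na(derived$omega_min)) derived$omega_min else omega_min
  if (is.null(om)) stop("no omega_min derived; supply one explicitly")
  tolerance_limits(derived$T_min, derived$T_max, derived$S_min, derived$S_max,
                   derived$NO3_max, derived$PO4_max, om, I_min)
}
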