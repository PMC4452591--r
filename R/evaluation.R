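#' Presence/absence matrix from habitat fractions
#'
#' 1 where the habitat (or observed reef) fraction is strictly above 0,
#' else 0.
#'
#' @param fraction A `reef_raster` of fractions in `[0, 1]` (NA treated as 0).
#' @return A binary `reef_raster` on the same grid.
#' @export
presence_matrix <- function(fraction) {
  stopifnot(inherits(fraction, "reef_raster"))
  v <- fraction$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("fractions must lie in [0, 1]")
  out <- ifelse(!is.na(v) & v > 0, 1, 0)
  raster_grid(fraction$spec, out)
}

#' Confusion counts between observed and predicted presence
#'
#' Subtracting the predicted from the observed binary matrix gives a signed
#' map with -1 (false positive: predicted suitable, no observed reef),
#' +1 (false negative: observed reef, predicted unsuitable) and 0 (match,
#' a true positive where observed = 1 and a true negative where observed
#' = 0). Cells with wholly missing environments count as true negatives when
#' both matrices are 0 there.
#'
#' @param observed,predicted Binary `reef_raster` layers on the same grid.
#' @return An object of class `confusion_counts`: integers `TP`, `FP`, `FN`,
#'   `TN` (summing to the number of evaluated cells) and `signed_map`, the
#'   -1/0/+1 `reef_raster` for plotting.
#' @export
confusion <- function(observed, predicted) {
  stopifnot(inherits(observed, "reef_raster"), inherits(predicted, "reef_raster"))
  if (!same_spec(observed$spec, predicted$spec))
    stop("observed and predicted grids differ")
  o <- observed$values; p <- predicted$values
  o[is.na(o)] <- 0; p[is.na(p)] <- 0
  if (!all(o %in% c(0, 1)) || !all(p %in% c(0, 1)))
    stop("matrices must be binary")
  d <- o - p
  structure(list(TP = sum(d == 0 & o == 1), FP = sum(d == -1),
                 FN = sum(d == 1), TN = sum(d == 0 & o == 0),
                 signed_map = raster_grid(observed$spec, d)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' True-positive and false-positive rates
#'
#' `TPR = TP / (TP + FN)` and `FPR = FP / (FP + TN)`.
#'
#' @param counts A [confusion()] result.
#' @return Named numeric vector `c(TPR = , FPR = )`.
#' @export
rates <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  P <- counts$TP + counts$FN
  N <- counts$FP + counts$TN
  if (P == 0 || N == 0)
    stop("rates undefined: world has no positives or no negatives")
  c(TPR = counts$TP / P, FPR = counts$FP / N)
}

#' Distance to the perfect-classification point
#'
#' Euclidean distance from the operating point (FPR, TPR) to the perfect
#' corner (0, 1) of the ROC graph: `sqrt(FPR^2 + (1 - TPR)^2)`.
#'
#' @param TPR,FPR Rates in `[0, 1]`.
#' @return Non-negative distance (0 at (0,1); `sqrt(2)` at (1,0)).
#' @export
roc_distance <- function(TPR, FPR) {
  sqrt(FPR^2 + (1 - TPR)^2)
}

# Precomputed sweep state: per-fine-cell critical irradiance. A fine cell
# with depth Z under a 5' cell (PAR, K490) satisfies 0 < Z <= Z_max(I) exactly
# when I <= PAR * exp(-K490 * Z), so one pass yields every sweep point.
sweep_state <- function(env, limits, omega_mask = NULL) {
  cenv <- coarse_env_ok(env, limits, omega_mask)
  f_med <- check_nesting(env$PAR$spec, env$temperature$spec)
  f_fine <- check_nesting(env$Z$spec, env$PAR$spec)
  par_f <- expand_matrix(env$PAR$values, f_fine)
  k_f <- expand_matrix(env$K490$values, f_fine)
  env_f <- expand_matrix(cenv$ok, f_med * f_fine)
  z <- env$Z$values
  crit <- par_f * exp(-k_f * z)
  crit[is.na(crit) | is.na(z) | z <= 0 | !env_f] <- -Inf
  list(crit = crit, areas = cell_areas(env$Z$spec),
       coarse = env$temperature$spec, fine = env$Z$spec,
       f_tot = f_med * f_fine)
}

sweep_point <- function(state, I, observed_presence) {
  fine_mask <- state$crit >= I
  frac <- aggregate_fraction(raster_grid(state$fine, fine_mask), state$coarse)
  cc <- confusion(observed_presence, presence_matrix(frac))
  r <- rates(cc)
  data.frame(I_min = I, TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
             TPR = r["TPR"], FPR = r["FPR"],
             distance = roc_distance(r["TPR"], r["FPR"]),
             area_km2 = sum(state$areas[fine_mask]), row.names = NULL)
}

#' Optimize the minimum light intensity by ROC sweep
#'
#' Runs the habitat prediction at each candidate `I_min` (all non-light
#' checks are computed once and reused; only the light criterion is
#' re-evaluated), compares 1-degree presence against observed reefs, and
#' picks the `I_min` whose operating point is closest to the perfect
#' classification corner (0, 1). The default protocol evaluates a coarse
#' grid of 50 to 500 in steps of 50, then refines with `refine_step` across
#' the interval bracketing the coarse optimum. Ties in distance go to the
#' smaller (less restrictive) `I_min`. Along any sweep FP is non-increasing
#' and FN non-decreasing, since raising `I_min` only shrinks the suitable
#' set.
#'
#' @param env An [env_stack()].
#' @param limits A [tolerance_limits()] (its `I_min` entry is ignored here).
#' @param observed A binary `reef_raster` of observed 1-degree presence, or a
#'   [rasterize_reefs()] result.
#' @param omega_mask Optional [region_mask()].
#' @param grid Strictly increasing candidate `I_min` values
#'   (umol photons m^-2 s^-1).
#' @param refine_step Step of the refinement pass; `NULL` disables
#'   refinement.
#' @return An object of class `imin_sweep`: `points` (data frame with
#'   `I_min`, `TP`, `FP`, `FN`, `TN`, `TPR`, `FPR`, `distance`, `area_km2`,
#'   ordered by `I_min`) and `best_I_min`.
#' @export
sweep_imin <- function(env, limits, observed, omega_mask = NULL,
                       grid = seq(50, 500, by = 50), refine_step = 10) {
  stopifnot(inherits(env, "env_stack"))
  if (inherits(observed, "reef_observations"))
    observed <- observed$coarse_fraction
  observed <- presence_matrix(observed)
  if (length(grid) == 0 || is.unsorted(grid, strictly = TRUE))
    stop("grid must be non-empty and strictly increasing")
  state <- sweep_state(env, limits, omega_mask)
  pts <- do.call(rbind, lapply(grid, sweep_point, state = state,
                               observed_presence = observed))
  best <- pts$I_min[which.min(pts$distance)]    # which.min takes first = smallest
  if (!is.null(refine_step)) {
    i <- match(best, grid)
    lo <- if (i > 1) grid[i - 1] else grid[i]
    hi <- if (i < length(grid)) grid[i + 1] else grid[i]
    fine_grid <- setdiff(seq(lo, hi, by = refine_step), pts$I_min)
    if (length(fine_grid)) {
      pts <- rbind(pts, do.call(rbind, lapply(fine_grid, sweep_point,
                                              state = state,
                                              observed_presence = observed)))
      pts <- pts[order(pts$I_min), ]
      rownames(pts) <- NULL
    }
  }
  structure(list(points = pts, best_I_min = pts$I_min[which.min(pts$distance)]),
            class = "imin_sweep")
}

#' @export
print.imin_sweep <- function(x, ...) {
  cat(sprintf("imin_sweep: %d points, best I_min = %g (distance %.4f)\n",
              nrow(x$points), x$best_I_min,
              min(x$points$distance)))
  invisible(x)
}
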