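#' Configuration for a synthetic world
#'
#' Defines the study conditions for a generated test world: extent, planted
#' tolerance limits (the ground truth to recover), noise amplitudes,
#' reef-placement density, and the rates of observational imperfection -
#' `omission_rate` (suitable cells left reef-free, emulating uncharted
#' reefs) and `commission_rate` (reef polygons dropped into deep, light-
#' unsuitable water, emulating the depth/reef mismatches of charted data).
#'
#' @param extent `c(lat_min, lat_max, lon_min, lon_max)` in degrees, within
#'   the 40 N - 40 S band; defaults to a 10 x 20 degree world (200 coarse
#'   cells, 2.88 million 30'' cells).
#' @param seed Integer seed fixing every random draw.
#' @param planted_limits A [tolerance_limits()]; defaults to
#'   [default_limits()].
#' @param noise Named list of noise amplitudes per variable (see Details).
#' @param reef_density Fraction (0-1] of eligible deep-ocean cells planted
#'   with robust reef habitat.
#' @param omission_rate,commission_rate Rates in `[0, 1]`.
#' @details Default noise amplitudes: temperature 0.25 degC, salinity 1 psu,
#'   NO3 0.8, PO4 0.05 umol/L, TA/DIC 25 umol/kg, PAR 30, K490 0.008,
#'   abyssal relief 300 m.
#' @return An object of class `world_config`.
#' @export
world_config <- function(extent = c(-5, 5, 0, 20), seed = 1L,
                         planted_limits = default_limits(),
                         noise = list(), reef_density = 1,
                         omission_rate = 0.1, commission_rate = 0.05) {
  stopifnot(length(extent) == 4, inherits(planted_limits, "tolerance_limits"))
  if (omission_rate < 0 || omission_rate > 1 ||
      commission_rate < 0 || commission_rate > 1)
    stop("rates must lie in [0, 1]")
  if (reef_density <= 0 || reef_density > 1)
    stop("reef_density must lie in (0, 1]")
  defaults <- list(temperature = 0.25, salinity = 1.0, NO3 = 0.8, PO4 = 0.05,
                   TA = 25, DIC = 25, PAR = 30, K490 = 0.008, Z = 300)
  noise <- utils::modifyList(defaults, noise)
  structure(list(extent = extent, seed = as.integer(seed),
                 planted_limits = planted_limits, noise = noise,
                 reef_density = reef_density,
                 omission_rate = omission_rate,
                 commission_rate = commission_rate),
            class = "world_config")
}

# smooth low-order harmonic noise; coefficients drawn from the current RNG
# stream, scaled so the field spans roughly [-amp, amp]
harmonic_field <- function(n_lat, n_lon, amp, n_harm = 3) {
  x <- matrix(seq_len(n_lon) / n_lon, n_lat, n_lon, byrow = TRUE)
  y <- matrix(seq_len(n_lat) / n_lat, n_lat, n_lon)
  f <- matrix(0, n_lat, n_lon)
  for (k in seq_len(n_harm)) {
    a <- stats::runif(1, 0.3, 1)
    p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
    f <- f + a * sin(2 * pi * k * x + p1) * cos(2 * pi * k * y + p2)
  }
  m <- max(abs(f))
  if (m > 0) f <- f / m
  amp * f
}

box_cells <- function(spec, lat_lo, lat_hi, lon_lo, lon_hi) {
  lat <- lat_centers(spec); lon <- lon_centers(spec)
  outer(lat >= lat_lo & lat < lat_hi, lon >= lon_lo & lon < lon_hi, "&")
}

# solve DIC so that omega_ara(TA, DIC, T, S) equals target
dic_for_omega <- function(TA, temperature, salinity, target, tol = 1e-12) {
  f <- function(DIC)
    solve_carbonate_system(TA, DIC, temperature, salinity)$omega_ara - target
  stats::uniroot(f, c(1200, TA * 0.999), tol = tol)$root
}

#' Generate a synthetic world with planted ground truth
#'
#' Builds co-registered environmental rasters at the three model resolutions
#' over the configured extent: temperature with a latitudinal gradient plus
#' smooth harmonic noise spanning beyond the planted temperature range (so
#' both bounds bind), salinity/nutrient/carbon fields likewise crossing
#' their thresholds in designated regions, PAR and K490 at 5' with coastal
#' attenuation elevation, and 30'' bathymetry with a coastal shelf
#' (roughly 3-58 m), a slope, and abyssal cells. Reef polygons are planted
#' with at least one vertex per chosen suitable cell, minus omissions, plus
#' commissions over deep water. Each planted tolerance bound is inserted
#' exactly at one designated reef cell, so inverse-mode recovery is exact;
#' the omega_ara bound is planted by solving DIC at one reef cell and the
#' realized saturation state is recorded in the truth. A ladder of
#' single-pixel shallow sites with critical irradiances spaced through the
#' sweep range, plus marginal reef sites just above the planted `I_min`,
#' makes the ROC sweep recover the planted optimum.
#'
#' @param config A [world_config()].
#' @return An object of class `synthetic_world`: `env` (an [env_stack()]
#'   including omega, TA, DIC, monthly and weekly layers), `reefs` (polygon
#'   vertex data frame), `config`, and `truth` (list: `limits` with the
#'   realized omega bound, `I_min`, `fine_mask`, `coarse_fraction`,
#'   `total_area_km2`, `reef_cells`, `n_omitted`, `n_commission`).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  ex <- config$extent
  if (ex[2] - ex[1] < 2 || ex[4] - ex[3] < 4)
    stop("degenerate extent: need at least 2 degrees of latitude and 4 of longitude")
  lim <- config$planted_limits
  nz <- config$noise
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  coarse <- grid_spec(ex[1], ex[2], ex[3], ex[4], 1)
  med <- grid_spec(ex[1], ex[2], ex[3], ex[4], 1 / 12)
  fine <- grid_spec(ex[1], ex[2], ex[3], ex[4], 1 / 120)
  nr <- coarse$n_lat; nc <- coarse$n_lon
  lat_c <- matrix(lat_centers(coarse), nr, nc)
  dlat <- ex[2] - ex[1]; dlon <- ex[4] - ex[3]

  # --- coarse environmental fields (1 degree) ---
  T_top <- lim$T_max + 0.7; T_bot <- lim$T_min - 1.7
  temperature <- T_top + (T_bot - T_top) * (lat_c - ex[1]) / dlat +
    harmonic_field(nr, nc, nz$temperature)
  salinity <- 34.5 + harmonic_field(nr, nc, nz$salinity)
  fresh <- box_cells(coarse, ex[1] + 0.6 * dlat, ex[1] + 0.9 * dlat,
                     ex[3] + 0.15 * dlon, ex[3] + 0.3 * dlon)
  salty <- box_cells(coarse, ex[1] + 0.1 * dlat, ex[1] + 0.4 * dlat,
                     ex[3] + 0.7 * dlon, ex[3] + 0.85 * dlon)
  salinity[fresh] <- salinity[fresh] - (salinity[fresh] - lim$S_min) - 1.5
  salinity[salty] <- lim$S_max + 0.7 + harmonic_field(nr, nc, 0.2)[salty]
  NO3 <- pmax(1.2 + harmonic_field(nr, nc, nz$NO3), 0.3)
  PO4 <- pmax(0.055 * NO3 + harmonic_field(nr, nc, nz$PO4), 0.02)
  upwell <- box_cells(coarse, ex[1] + 0.75 * dlat, ex[2],
                      ex[3] + 0.85 * dlon, ex[4])
  NO3[upwell] <- NO3[upwell] + lim$NO3_max + 1
  PO4[upwell] <- PO4[upwell] + lim$PO4_max + 0.2
  TA <- 2320 + harmonic_field(nr, nc, nz$TA)
  DIC <- 1950 + 6 * abs(lat_c) + harmonic_field(nr, nc, nz$DIC)
  sour <- box_cells(coarse, ex[1], ex[1] + 0.3 * dlat,
                    ex[3] + 0.4 * dlon, ex[3] + 0.55 * dlon)
  DIC[sour] <- DIC[sour] + 150

  # --- 5' light fields ---
  lat_m <- matrix(lat_centers(med), med$n_lat, med$n_lon)
  lon_m <- matrix(lon_centers(med), med$n_lat, med$n_lon, byrow = TRUE)
  PAR <- 1900 - 6 * abs(lat_m) + harmonic_field(med$n_lat, med$n_lon, nz$PAR)
  K490 <- 0.05 + harmonic_field(med$n_lat, med$n_lon, nz$K490) +
    0.05 * exp(-(lon_m - ex[3]) / 1.5)

  # --- 30'' bathymetry: land strip, shelf, slope, abyss ---
  lon_f <- matrix(lon_centers(fine), fine$n_lat, fine$n_lon, byrow = TRUE)
  relief <- harmonic_field(fine$n_lat, fine$n_lon, 1)
  d_coast <- lon_f - ex[3]
  Z <- 4000 + nz$Z * relief                           # abyss
  slope <- d_coast >= 2 & d_coast < 3
  Z[slope] <- 60 + 2140 * (d_coast[slope] - 2)
  shelf <- d_coast >= 1 & d_coast < 2
  Z[shelf] <- pmax(0.5, 3 + 52 * (d_coast[shelf] - 1) + 2 * relief[shelf])
  land <- d_coast < 1
  Z[land] <- -(10 + 5 * abs(relief[land]))

  omega <- omega_field(raster_grid(coarse, TA), raster_grid(coarse, DIC),
                       raster_grid(coarse, temperature),
                       raster_grid(coarse, salinity))$values

  # --- envelope-suitable set and site designation ---
  env_ok <- check_env_cell(temperature, salinity, NO3, PO4, omega, lim)
  eligible <- which(env_ok & col(env_ok) >= 4)        # abyss-backed cells
  eligible <- eligible[sample.int(length(eligible))]  # seeded shuffle
  ladder_crit <- seq(55, 445, by = 10)
  n_marginal <- 8L
  n_floor <- n_marginal + 10L + 8L        # marginal + robust/commission + ladder
  if (length(eligible) < n_floor)
    stop(sprintf("degenerate extent: only %d eligible cells, need >= %d",
                 length(eligible), n_floor))
  # thin the irradiance ladder on small domains, keeping its even spread
  n_ladder <- min(length(ladder_crit), length(eligible) - n_marginal - 10L)
  ladder_crit <- ladder_crit[unique(round(seq(1, length(ladder_crit),
                                              length.out = n_ladder)))]
  idx_ladder <- eligible[seq_along(ladder_crit)]
  idx_marginal <- eligible[length(ladder_crit) + seq_len(n_marginal)]
  rest <- eligible[-(seq_len(length(ladder_crit) + n_marginal))]
  n_robust <- max(8L, round(config$reef_density * length(rest) * 0.5))
  idx_robust <- rest[seq_len(min(n_robust, length(rest)))]

  # carve one precisely-calibrated shallow pixel per designated cell:
  # depth such that the cell's critical irradiance equals crit
  f_tot <- 120L; f_med <- 10L
  pixel_of <- function(idx) {
    r <- (idx - 1) %% nr + 1; c <- (idx - 1) %/% nr + 1
    c(r = (r - 1) * f_tot + f_tot / 2, c = (c - 1) * f_tot + f_tot / 2)
  }
  plant_pixel <- function(idx, crit) {
    p <- pixel_of(idx)
    rm_ <- (p["r"] - 1) %/% f_med + 1; cm_ <- (p["c"] - 1) %/% f_med + 1
    depth <- log(PAR[rm_, cm_] / crit) / K490[rm_, cm_]
    Z[p["r"], p["c"]] <<- depth
    p
  }
  for (i in seq_along(idx_ladder)) plant_pixel(idx_ladder[i], ladder_crit[i])
  marginal_crit <- lim$I_min + 2
  marg_px <- lapply(idx_marginal, plant_pixel, crit = marginal_crit)
  robust_px <- lapply(idx_robust, plant_pixel, crit = lim$I_min + 250)

  # --- suitable set at the planted I_min; reef cells = suitable - omissions
  mk_env <- function() {
    env_stack(
      temperature = raster_grid(coarse, temperature),
      salinity = raster_grid(coarse, salinity),
      NO3 = raster_grid(coarse, NO3), PO4 = raster_grid(coarse, PO4),
      PAR = raster_grid(med, PAR), K490 = raster_grid(med, K490),
      Z = raster_grid(fine, Z),
      omega = raster_grid(coarse, omega),
      TA = raster_grid(coarse, TA), DIC = raster_grid(coarse, DIC),
      monthly = monthly, weekly_T = weekly_T)
  }
  monthly <- NULL; weekly_T <- NULL
  pred0 <- predict_habitat(mk_env(), lim)
  suitable <- which(pred0$coarse_fraction$values > 0)

  # bound-planting cells come from the robust set and are never omitted
  bound_cells <- idx_robust[seq_len(7)]
  removable <- setdiff(suitable, bound_cells)
  n_omit <- round(config$omission_rate * length(suitable))
  omitted <- if (n_omit > 0)
    removable[sample.int(length(removable), min(n_omit, length(removable)))]
  else integer(0)
  reef_cells <- setdiff(suitable, omitted)

  n_comm <- round(config$commission_rate * length(reef_cells))
  comm_pool <- setdiff(rest[-seq_len(min(n_robust, length(rest)))], suitable)
  commission <- if (n_comm > 0 && length(comm_pool))
    comm_pool[seq_len(min(n_comm, length(comm_pool)))]
  else integer(0)

  # --- clamp environments at reef + commission cells strictly inside the
  #     envelope, then insert each bound exactly once ---
  touched <- c(reef_cells, commission)
  temperature[touched] <- pmin(pmax(temperature[touched], lim$T_min + 0.4),
                               lim$T_max - 0.4)
  salinity[touched] <- pmin(pmax(salinity[touched], lim$S_min + 0.8),
                            lim$S_max - 0.8)
  NO3[touched] <- pmin(NO3[touched], lim$NO3_max - 0.4)
  PO4[touched] <- pmin(PO4[touched], lim$PO4_max - 0.06)
  temperature[bound_cells[1]] <- lim$T_min
  temperature[bound_cells[2]] <- lim$T_max
  salinity[bound_cells[3]] <- lim$S_min
  salinity[bound_cells[4]] <- lim$S_max
  NO3[bound_cells[5]] <- lim$NO3_max
  PO4[bound_cells[6]] <- lim$PO4_max

  # saturation state: lift marginal reef/commission cells clear of the
  # threshold, then plant the exact bound at one designated cell
  omega[touched] <- solve_carbonate_system(
    TA[touched], DIC[touched], temperature[touched], salinity[touched])$omega_ara
  lift <- touched[omega[touched] < lim$omega_min + 0.05]
  for (i in lift) {
    DIC[i] <- dic_for_omega(TA[i], temperature[i], salinity[i],
                            lim$omega_min + 0.1, tol = 1e-8)
  }
  ob <- bound_cells[7]
  DIC[ob] <- dic_for_omega(TA[ob], temperature[ob], salinity[ob], lim$omega_min)
  # keep the realized value at-or-above the bound (inclusive envelope check)
  repeat {
    o_ob <- solve_carbonate_system(TA[ob], DIC[ob], temperature[ob],
                                   salinity[ob])$omega_ara
    if (o_ob >= lim$omega_min) break
    DIC[ob] <- DIC[ob] - 1e-6
  }
  omega <- omega_field(raster_grid(coarse, TA), raster_grid(coarse, DIC),
                       raster_grid(coarse, temperature),
                       raster_grid(coarse, salinity))$values
  realized_omega_min <- omega[ob]

  # --- time-resolved layers: seasonal cycles around the annual mean ---
  phase <- ifelse(lat_c < 0, pi, 0)
  cyc <- function(base, amp, n, t) base + amp * cos(2 * pi * (t - 0.5) / n + phase)
  monthly <- list(
    temperature = lapply(1:12, function(m)
      raster_grid(coarse, cyc(temperature, 2.5, 12, m))),
    salinity = lapply(1:12, function(m)
      raster_grid(coarse, cyc(salinity, 0.8, 12, m))),
    NO3 = lapply(1:12, function(m)
      raster_grid(coarse, NO3 * (1 + 0.25 * cos(2 * pi * (m - 0.5) / 12 + phase)))),
    PO4 = lapply(1:12, function(m)
      raster_grid(coarse, PO4 * (1 + 0.25 * cos(2 * pi * (m - 0.5) / 12 + phase)))))
  weekly_T <- lapply(1:52, function(w)
    raster_grid(coarse, cyc(temperature, 3.5, 52, w)))

  env <- mk_env()
  result <- predict_habitat(env, lim)
  stopifnot(all(reef_cells %in% which(result$coarse_fraction$values > 0)))

  # --- reef polygons: one small quad per reef cell, vertex on a suitable
  #     pixel; commissions sit over abyssal water ---
  px_lookup <- c(
    stats::setNames(marg_px, idx_marginal),
    stats::setNames(robust_px, idx_robust))
  vertex_pixel <- function(idx) {
    key <- as.character(idx)
    if (!is.null(px_lookup[[key]])) return(px_lookup[[key]])
    r <- (idx - 1) %% nr + 1; c <- (idx - 1) %/% nr + 1
    rows <- (r - 1) * f_tot + seq_len(f_tot)
    cols <- (c - 1) * f_tot + seq_len(f_tot)
    block <- Z[rows, cols]
    block[block <= 0] <- Inf
    j <- which.min(block)            # shallowest wet pixel, first on ties
    c(r = rows[(j - 1) %% f_tot + 1], c = cols[(j - 1) %/% f_tot + 1])
  }
  quad <- function(id, px) {
    res <- fine$resolution
    lat0 <- fine$lat_min + (px["r"] - 0.5) * res
    lon0 <- fine$lon_min + (px["c"] - 0.5) * res
    data.frame(polygon_id = id,
               lat = lat0 + c(-0.3, 0, 0.3, 0) * res,
               lon = lon0 + c(0, 0.3, 0, -0.3) * res)
  }
  polys <- list(); id <- 0L
  for (idx in sort(reef_cells)) {
    id <- id + 1L
    polys[[id]] <- quad(id, vertex_pixel(idx))
  }
  for (idx in sort(commission)) {
    id <- id + 1L
    polys[[id]] <- quad(id, pixel_of(idx))
  }
  reefs <- do.call(rbind, polys)
  rownames(reefs) <- NULL

  truth_limits <- tolerance_limits(lim$T_min, lim$T_max, lim$S_min, lim$S_max,
                                   lim$NO3_max, lim$PO4_max,
                                   realized_omega_min, lim$I_min)
  structure(list(
    env = env, reefs = reefs, config = config,
    truth = list(limits = truth_limits, I_min = lim$I_min,
                 fine_mask = result$fine_mask,
                 coarse_fraction = result$coarse_fraction,
                 total_area_km2 = result$total_area_km2,
                 reef_cells = sort(reef_cells),
                 n_omitted = length(omitted),
                 n_commission = length(commission))),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_world (seed %d): %d x %d degrees, %d reef cells ",
    "(%d omitted, %d commissions), truth area %.1f km^2 at I_min = %g\n"),
    x$config$seed, x$env$temperature$spec$n_lat, x$env$temperature$spec$n_lon,
    length(x$truth$reef_cells), x$truth$n_omitted, x$truth$n_commission,
    x$truth$total_area_km2, x$truth$I_min))
  invisible(x)
}
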