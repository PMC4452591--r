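# shared fixtures built in code

# small 2 x 2 degree stack with direct control over every layer; defaults are
# uniformly suitable under default_limits() with a flat 10 m shelf
tiny_world <- function(temperature = 26, salinity = 35, NO3 = 1, PO4 = 0.1,
                       omega = 3.5, PAR = 1800, K490 = 0.05, Z = 10,
                       lat0 = -1, lon0 = 0) {
  coarse <- grid_spec(lat0, lat0 + 2, lon0, lon0 + 2, 1)
  med <- grid_spec(lat0, lat0 + 2, lon0, lon0 + 2, 1 / 12)
  fine <- grid_spec(lat0, lat0 + 2, lon0, lon0 + 2, 1 / 120)
  as_r <- function(x, spec) {
    if (length(x) == 1) x <- matrix(x, spec$n_lat, spec$n_lon)
    raster_grid(spec, x)
  }
  env_stack(temperature = as_r(temperature, coarse),
            salinity = as_r(salinity, coarse),
            NO3 = as_r(NO3, coarse), PO4 = as_r(PO4, coarse),
            PAR = as_r(PAR, med), K490 = as_r(K490, med),
            Z = as_r(Z, fine),
            omega = if (is.null(omega)) NULL else as_r(omega, coarse))
}

# randomized tiny world: environmental values straddling the envelope,
# bathymetry mixing land, shelf and deep water
random_tiny_world <- function(seed) {
  set.seed(seed)
  lim <- default_limits()
  n <- 4   # 2 x 2 coarse cells
  rm_ <- function(lo, hi, spec) matrix(stats::runif(spec$n_lat * spec$n_lon, lo, hi),
                                       spec$n_lat, spec$n_lon)
  coarse <- grid_spec(-1, 1, 0, 2, 1)
  med <- grid_spec(-1, 1, 0, 2, 1 / 12)
  fine <- grid_spec(-1, 1, 0, 2, 1 / 120)
  Z <- rm_(-50, 80, fine)
  Z[stats::runif(length(Z)) < 0.02] <- NA
  env_stack(
    temperature = raster_grid(coarse, rm_(lim$T_min - 2, lim$T_max + 2, coarse)),
    salinity = raster_grid(coarse, rm_(lim$S_min - 2, lim$S_max + 2, coarse)),
    NO3 = raster_grid(coarse, rm_(0, lim$NO3_max * 1.5, coarse)),
    PO4 = raster_grid(coarse, rm_(0, lim$PO4_max * 1.5, coarse)),
    PAR = raster_grid(med, rm_(300, 2200, med)),
    K490 = raster_grid(med, rm_(0.02, 0.15, med)),
    Z = raster_grid(fine, Z),
    omega = raster_grid(coarse, rm_(lim$omega_min - 0.5, lim$omega_min + 1.5, coarse)))
}

# the reference synthetic world, generated once per test run
ref_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_world(world_config(seed = 101L))
    cache
  }
})

ref_observations <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- ref_world()
      cache <<- rasterize_reefs(w$reefs, w$env$Z$spec)
    }
    cache
  }
})
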