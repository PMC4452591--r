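# Independent oracles: literal re-implementations used only to cross-check
# package results. They deliberately share no code with the package.

# spherical cell area by numerical integration of R^2 cos(phi) dphi dlambda
oracle_cell_area <- function(lat_lo, lat_hi, dlon) {
  R <- 6371.0
  f <- stats::integrate(function(phi) cos(phi), lat_lo * pi / 180,
                        lat_hi * pi / 180, rel.tol = 1e-13)
  R^2 * (dlon * pi / 180) * f$value
}

# literal per-cell evaluation of the decision flow at 30'' resolution;
# rows/cols restrict the evaluation window (fine indices)
oracle_predict <- function(env, limits, omega_mask = NULL,
                           rows = NULL, cols = NULL) {
  fs <- env$Z$spec
  if (is.null(rows)) rows <- seq_len(fs$n_lat)
  if (is.null(cols)) cols <- seq_len(fs$n_lon)
  f_c <- round(1 / fs$resolution)          # fine cells per degree
  f_m <- round((1 / 12) / fs$resolution)   # fine cells per 5' cell
  out <- matrix(FALSE, length(rows), length(cols))
  in_mask <- function(lat, lon) {
    if (is.null(omega_mask)) return(FALSE)
    any(lat >= omega_mask$lat_min & lat < omega_mask$lat_max &
          lon >= omega_mask$lon_min & lon < omega_mask$lon_max)
  }
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      r <- rows[i]; c <- cols[j]
      z <- env$Z$values[r, c]
      if (is.na(z) || z <= 0) next
      cr <- ceiling(r / f_c); cc <- ceiling(c / f_c)
      Tv <- env$temperature$values[cr, cc]
      Sv <- env$salinity$values[cr, cc]
      Nv <- env$NO3$values[cr, cc]
      Pv <- env$PO4$values[cr, cc]
      if (is.na(Tv) || Tv < limits$T_min || Tv > limits$T_max) next
      if (is.na(Sv) || Sv < limits$S_min || Sv > limits$S_max) next
      if (is.na(Nv) || Nv > limits$NO3_max) next
      if (is.na(Pv) || Pv > limits$PO4_max) next
      lat_ctr <- env$temperature$spec$lat_min + (cr - 0.5)
      lon_ctr <- env$temperature$spec$lon_min + (cc - 0.5)
      if (!is.null(env$omega) && !in_mask(lat_ctr, lon_ctr)) {
        ov <- env$omega$values[cr, cc]
        if (!is.na(ov) && ov < limits$omega_min) next
      }
      mr <- ceiling(r / f_m); mc <- ceiling(c / f_m)
      PARv <- env$PAR$values[mr, mc]; Kv <- env$K490$values[mr, mc]
      if (is.na(PARv) || is.na(Kv)) next
      zmax <- if (PARv > limits$I_min) log(PARv / limits$I_min) / Kv else 0
      out[i, j] <- z <= zmax
    }
  }
  out
}

# cell-by-cell confusion tally
oracle_confusion <- function(obs, pred) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(obs)) {
    if (obs[i] == 1 && pred[i] == 1) tp <- tp + 1L
    else if (obs[i] == 0 && pred[i] == 1) fp <- fp + 1L
    else if (obs[i] == 1 && pred[i] == 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}
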