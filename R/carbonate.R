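#' Seawater carbonate-system equilibrium constants
#'
#' Stoichiometric constants on the total pH scale at surface pressure (0 dbar),
#' the conventional open-ocean surface set: K1/K2 from Lueker et al. (2000),
#' boric acid KB from Dickson (1990), water KW from Millero (1995, seawater
#' scale, converted to total), aragonite and calcite solubility from Mucci
#' (1983), total boron from salinity after Uppstrom (1974), calcium
#' proportional to salinity (Riley & Tongudai). Bisulfate (Dickson 1990) and
#' fluoride (Dickson & Riley 1979) constants are carried only for the pH-scale
#' conversion of KW.
#'
#' @param temperature Temperature in degrees C (vectorized).
#' @param salinity Practical salinity, psu (vectorized).
#' @return List of numeric vectors: `K1`, `K2`, `KB`, `KW` (mol/kg, total
#'   scale), `KspA`, `KspC` ((mol/kg)^2), `TB`, `Ca` (mol/kg).
#' @export
carbonate_constants <- function(temperature, salinity) {
  T_K <- temperature + 273.15
  S <- salinity
  lnT <- log(T_K)
  sqS <- sqrt(S)
  pK1 <- 3633.86 / T_K - 61.2172 + 9.6777 * lnT - 0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / T_K + 25.929 - 3.16967 * lnT - 0.01781 * S + 0.0001122 * S^2
  lnKB <- (-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S^1.5 - 0.0996 * S^2) / T_K +
    148.0248 + 137.1942 * sqS + 1.62142 * S +
    (-24.4344 - 25.085 * sqS - 0.2474 * S) * lnT +
    0.053105 * sqS * T_K
  # KS (free scale) and KF only enter through the SWS -> total conversion of KW
  IonS <- 19.924 * S / (1000 - 1.005 * S)
  lnKS <- -4276.1 / T_K + 141.328 - 23.093 * lnT +
    (-13856 / T_K + 324.57 - 47.986 * lnT) * sqrt(IonS) +
    (35474 / T_K - 771.54 + 114.723 * lnT) * IonS -
    2698 / T_K * IonS^1.5 + 1776 / T_K * IonS^2
  KS <- exp(lnKS) * (1 - 0.001005 * S)
  KF <- exp(1590.2 / T_K - 12.641 + 1.525 * sqrt(IonS)) * (1 - 0.001005 * S)
  TS <- (0.14 / 96.062) * (S / 1.80655)
  TF <- (0.000067 / 18.998) * (S / 1.80655)
  lnKW <- 148.9802 - 13847.26 / T_K - 23.6521 * lnT +
    (118.67 / T_K - 5.977 + 1.0495 * lnT) * sqS - 0.01615 * S
  SWStoTOT <- (1 + TS / KS) / (1 + TS / KS + TF / KF)
  log10T <- log10(T_K)
  lKspC <- -171.9065 - 0.077993 * T_K + 2839.319 / T_K + 71.595 * log10T +
    (-0.77712 + 0.0028426 * T_K + 178.34 / T_K) * sqS -
    0.07711 * S + 0.0041249 * S^1.5
  lKspA <- -171.945 - 0.077993 * T_K + 2903.293 / T_K + 71.595 * log10T +
    (-0.068393 + 0.0017276 * T_K + 88.135 / T_K) * sqS -
    0.10018 * S + 0.0059415 * S^1.5
  list(K1 = 10^-pK1, K2 = 10^-pK2, KB = exp(lnKB), KW = exp(lnKW) * SWStoTOT,
       KspA = 10^lKspA, KspC = 10^lKspC,
       TB = 0.0004157 * S / 35,
       Ca = 0.02128 / 40.087 * (S / 1.80655))
}

# Modelled total alkalinity (mol/kg) and its derivative in H at given DIC.
# The alkalinity model is restricted to carbonate + borate + water
# contributions (nutrient and minor-acid terms neglected), an approximation
# appropriate at surface-ocean nutrient levels.
ta_model <- function(H, DIC, k) {
  denom <- H * H + k$K1 * H + k$K1 * k$K2
  DIC * (k$K1 * H + 2 * k$K1 * k$K2) / denom +
    k$TB * k$KB / (k$KB + H) + k$KW / H - H
}

ta_model_dH <- function(H, DIC, k) {
  denom <- H * H + k$K1 * H + k$K1 * k$K2
  d_hco3 <- DIC * k$K1 * (k$K1 * k$K2 - H * H) / denom^2
  d_co3 <- -2 * DIC * k$K1 * k$K2 * (2 * H + k$K1) / denom^2
  d_hco3 + d_co3 - k$TB * k$KB / (k$KB + H)^2 - k$KW / H^2 - 1
}

solve_one <- function(TA, DIC, k) {
  f <- function(H) ta_model(H, DIC, k) - TA
  H_lo <- 10^-12; H_hi <- 10^-2          # pH 12 .. 2
  f_lo <- f(H_lo); f_hi <- f(H_hi)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0)
    stop(sprintf(
      "carbonate solver: no root in pH [2, 12] for TA=%.6g, DIC=%.6g umol/kg",
      TA * 1e6, DIC * 1e6))
  # bracketed bisection (TA is monotone decreasing in H: f_lo > 0 > f_hi)
  for (i in 1:40) {
    H_mid <- sqrt(H_lo * H_hi)           # geometric midpoint: bisection in pH
    if (f(H_mid) > 0) H_lo <- H_mid else H_hi <- H_mid
  }
  # Newton refinement, safeguarded back into the bracket
  H <- sqrt(H_lo * H_hi)
  for (i in 1:30) {
    step <- f(H) / ta_model_dH(H, DIC, k)
    H_new <- H - step
    if (!is.finite(H_new) || H_new <= H_lo || H_new >= H_hi)
      H_new <- sqrt(H_lo * H_hi)
    if (f(H_new) > 0) H_lo <- H_new else H_hi <- H_new
    done <- abs(H_new - H) <= 1e-10 * H_new
    H <- H_new
    if (done) break
  }
  H
}

#' Solve the seawater CO2 system from total alkalinity and DIC
#'
#' Finds the hydrogen-ion concentration at which modelled total alkalinity
#' (carbonate + borate + water contributions) equals the input alkalinity at
#' the given DIC, by bracketed bisection on pH in `[2, 12]` refined with
#' safeguarded Newton steps to a relative tolerance of 1e-10 in H. Surface
#' pressure (0 dbar) and the total pH scale throughout.
#'
#' @param TA Total alkalinity, umol/kg (vectorized).
#' @param DIC Dissolved inorganic carbon, umol/kg (vectorized).
#' @param temperature Temperature, degrees C.
#' @param salinity Practical salinity, psu.
#' @return List of numeric vectors: `pH_total`, `CO3` (carbonate ion,
#'   umol/kg), `omega_ara` and `omega_cal` (aragonite and calcite saturation
#'   states, dimensionless). Aragonite is the more soluble polymorph, so
#'   `omega_cal > omega_ara` always.
#' @examples
#' st <- solve_carbonate_system(2300, 2000, 25, 35)
#' st$omega_ara
#' @export
solve_carbonate_system <- function(TA, DIC, temperature, salinity) {
  n <- max(length(TA), length(DIC), length(temperature), length(salinity))
  TA <- rep_len(TA, n); DIC <- rep_len(DIC, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  if (any(TA <= 0, na.rm = TRUE) || any(DIC <= 0, na.rm = TRUE))
    stop("TA and DIC must be positive")
  if (any(salinity <= 0 | salinity >= 50, na.rm = TRUE))
    stop("salinity must lie in (0, 50) psu")
  if (any(temperature <= -2 | temperature >= 40, na.rm = TRUE))
    stop("temperature must lie in (-2, 40) degrees C")
  pH <- CO3 <- oa <- oc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(TA[i]) || is.na(DIC[i]) || is.na(temperature[i]) || is.na(salinity[i]))
      next
    k <- carbonate_constants(temperature[i], salinity[i])
    H <- solve_one(TA[i] * 1e-6, DIC[i] * 1e-6, k)
    denom <- H * H + k$K1 * H + k$K1 * k$K2
    co3 <- DIC[i] * 1e-6 * k$K1 * k$K2 / denom
    pH[i] <- -log10(H)
    CO3[i] <- co3 * 1e6
    oa[i] <- k$Ca * co3 / k$KspA
    oc[i] <- k$Ca * co3 / k$KspC
  }
  list(pH_total = pH, CO3 = CO3, omega_ara = oa, omega_cal = oc)
}

#' Aragonite saturation state field from gridded TA and DIC
#'
#' Cellwise [solve_carbonate_system()] over co-registered rasters; any missing
#' input yields a missing output cell.
#'
#' @param TA,DIC,temperature,salinity `reef_raster` layers sharing one
#'   [grid_spec()] (TA, DIC in umol/kg; temperature in degrees C; salinity in
#'   psu).
#' @return A `reef_raster` of omega_ara on the same grid.
#' @export
omega_field <- function(TA, DIC, temperature, salinity) {
  rs <- list(TA, DIC, temperature, salinity)
  stopifnot(all(vapply(rs, inherits, logical(1), "reef_raster")))
  for (r in rs[-1])
    if (!same_spec(r$spec, TA$spec)) stop("all rasters must share one grid")
  out <- matrix(NA_real_, TA$spec$n_lat, TA$spec$n_lon)
  ok <- !(is.na(TA$values) | is.na(DIC$values) |
            is.na(temperature$values) | is.na(salinity$values))
  if (any(ok)) {
    st <- solve_carbonate_system(TA$values[ok], DIC$values[ok],
                                 temperature$values[ok], salinity$values[ok])
    out[ok] <- st$omega_ara
  }
  raster_grid(TA$spec, out)
}
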