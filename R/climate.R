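#' Monthly mean solar declination
#'
#' Annual harmonic approximation evaluated at the mid-month day of year:
#' `delta = -23.45 deg * cos(2*pi*(doy + 10)/365)`.
#'
#' @param month Integer month 1-12.
#' @return Declination in radians; magnitude never exceeds 23.45 degrees.
#' @examples
#' solar_declination(6) * 180 / pi
#' @export
solar_declination <- function(month) {
  if (any(!month %in% 1:12)) abort("`month` must be an integer in 1-12")
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  doy <- cumsum(days) - days / 2
  -23.45 * pi / 180 * cos(2 * pi * (doy[month] + 10) / 365)
}

#' Mean daytime temperature from the diurnal extremes
#'
#' Assumes a sinusoidal diurnal temperature cycle with daylight hours set by
#' latitude and solar declination:
#' `Tg = Tmax * w + Tmin * (1 - w)` with
#' `w = 1/2 + sqrt(1 - x^2) / (2 * acos(x))` and `x = -tan(lat) * tan(decl)`.
#' The weight on Tmax is at least 1/2, so the daytime mean never falls below
#' the diurnal mean.
#'
#' Polar cases: under 24-hour daylight (`x <= -1`) the continuous limit of
#' the weight is 1/2, so the daytime mean equals the diurnal mean; under
#' polar night (`x >= 1`) there is no daytime and `NA` is returned (such
#' months are excluded from the growing season).
#'
#' @param tmax,tmin Monthly mean daily maximum and minimum temperature,
#'   degrees C (`tmax >= tmin`).
#' @param lat Latitude, radians.
#' @param decl Solar declination, radians.
#' @return Daytime mean temperature, degrees C (NA for polar night).
#' @examples
#' daytime_temperature(30, 20, 0, 0) # 25 + 10/pi
#' @export
daytime_temperature <- function(tmax, tmin, lat, decl) {
  if (any(tmax < tmin)) abort("`tmax` must be >= `tmin`")
  x <- -tan(lat) * tan(decl)
  w <- ifelse(x <= -1, 0.5,
              ifelse(x >= 1, NA_real_,
                     0.5 + sqrt(pmax(1 - x^2, 0)) / (2 * acos(pmin(pmax(x, -1), 1)))))
  tmax * w + tmin * (1 - w)
}

#' Convert shortwave irradiance to photosynthetic photon flux density
#'
#' @param sw Downward shortwave irradiance, W/m2 (>= 0).
#' @param e2f Energy-to-flux conversion factor, umol/J.
#' @return PPFD, umol/m2/s.
#' @examples
#' ppfd_from_shortwave(1000)
#' @export
ppfd_from_shortwave <- function(sw, e2f = 2.04) {
  if (any(!is.finite(sw)) || any(sw < 0)) abort("`sw` must be >= 0")
  sw * e2f
}

#' Atmospheric pressure from elevation
#'
#' Standard-atmosphere barometric formula with a constant lapse rate:
#' `P = 101325 * (1 - L*z/T0)^(g*Md/(R*L))` with L = 0.0065 K/m,
#' T0 = 288.15 K, g = 9.80665 m/s2 and Md = 0.028963 kg/mol.
#'
#' @param z Elevation, m, in \[-500, 9000\].
#' @return Pressure, Pa; 101325 at z = 0, decreasing with elevation.
#' @examples
#' patm_from_elevation(c(0, 2500))
#' @export
patm_from_elevation <- function(z) {
  if (any(!is.finite(z)) || any(z < -500 | z > 9000)) {
    abort("`z` must lie in [-500, 9000] m")
  }
  .PATM0 * (1 - 0.0065 * z / 288.15)^(9.80665 * 0.028963 / (.R_GAS * 0.0065))
}

#' Vapour pressure deficit from diurnal extremes and specific humidity
#'
#' Magnus-Tetens saturation vapour pressure at the diurnal mean temperature,
#' `es = 0.611 * exp(17.27*T/(T + 237.3))` kPa with `T = (tmin + tmax)/2`,
#' and actual vapour pressure from the specific humidity,
#' `ea = patm * Wair * Rv / (Rd + Wair * Rv)` with `Wair = q/(1 - q)`,
#' `Rd = R/Md`, `Rv = R/Mv` (Md = 28.963, Mv = 18.02 g/mol). `D = es - ea`;
#' negative values (coarse humidity data implying supersaturation) are
#' clamped to zero with a warning giving the count.
#'
#' @inheritParams daytime_temperature
#' @param q_air Specific humidity, kg/kg, in \[0, 1).
#' @param patm Atmospheric pressure, Pa.
#' @return Vapour pressure deficit, kPa.
#' @examples
#' vpd(0, 0, 0, 101325) # = es(0 C) = 0.611 kPa
#' @export
vpd <- function(tmax, tmin, q_air, patm = .PATM0) {
  if (any(!is.finite(q_air)) || any(q_air < 0) || any(q_air >= 1)) {
    abort("`q_air` must lie in [0, 1)")
  }
  if (any(patm <= 0)) abort("`patm` must be positive")
  t_mean <- (tmin + tmax) / 2
  es <- 0.611 * exp(17.27 * t_mean / (t_mean + 237.3))
  rd <- .R_GAS / 0.028963
  rv <- .R_GAS / 0.01802
  wair <- q_air / (1 - q_air)
  ea <- patm * wair * rv / (rd + wair * rv) / 1000 # Pa -> kPa
  d <- es - ea
  n_neg <- sum(d < 0)
  if (n_neg > 0) {
    warn(sprintf("%d negative vapour pressure deficit value(s) clamped to 0",
                 n_neg))
  }
  pmax(d, 0)
}

#' Growing-season climate drivers from monthly climate
#'
#' Aggregates 12 monthly rows per site into the drivers of the optimality
#' model. The thermal growing season comprises months whose mean daily
#' temperature `(tmax + tmin)/2` exceeds 0 degrees C (polar-night months are
#' also excluded). Over those months, `tg_c` is the mean of the monthly
#' daytime temperature ([daytime_temperature()]), `ppfd` and `d_kpa` are
#' plain means (monthly D is computed first, then averaged), and `patm_pa`
#' comes from the site elevation.
#'
#' @param monthly Data frame with columns `site_id`, `lat` (degrees),
#'   `elevation_m`, `month`, `tmax_c`, `tmin_c`, `q_air` and either `sw_wm2`
#'   or `ppfd`.
#' @param d_floor_kpa Lower bound applied to the aggregated vapour pressure
#'   deficit so that its logarithm stays finite downstream.
#' @param params A [kinetic_params()] set (supplies the energy-to-flux
#'   factor).
#' @return Tibble with one row per site: `site_id`, `tg_c`, `ppfd`, `d_kpa`,
#'   `patm_pa`, `n_months_used`.
#' @examples
#' m <- tibble::tibble(site_id = "a", lat = 0, elevation_m = 0,
#'                     month = 1:12, tmax_c = 28, tmin_c = 18,
#'                     sw_wm2 = 200, q_air = 0.008)
#' growing_season_climate(m)
#' @export
growing_season_climate <- function(monthly, d_floor_kpa = 0.01,
                                   params = kinetic_params()) {
  needed <- c("site_id", "lat", "elevation_m", "month", "tmax_c", "tmin_c",
              "q_air")
  missing_cols <- setdiff(needed, names(monthly))
  if (length(missing_cols)) {
    abort(paste0("`monthly` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!any(c("ppfd", "sw_wm2") %in% names(monthly))) {
    abort("`monthly` needs either a `ppfd` or an `sw_wm2` column")
  }
  m <- as_tibble(monthly)
  if (!"ppfd" %in% names(m)) {
    m$ppfd <- ppfd_from_shortwave(m$sw_wm2, params$e2f)
  }
  m <- dplyr::mutate(
    m,
    patm_pa = patm_from_elevation(.data$elevation_m),
    tg_month = daytime_temperature(.data$tmax_c, .data$tmin_c,
                                   .data$lat * pi / 180,
                                   solar_declination(.data$month)),
    d_month = vpd(.data$tmax_c, .data$tmin_c, .data$q_air, .data$patm_pa),
    qualifies = (.data$tmax_c + .data$tmin_c) / 2 > 0 & !is.na(.data$tg_month)
  )
  empty <- dplyr::filter(dplyr::summarise(dplyr::group_by(m, .data$site_id),
                                          any_gs = any(.data$qualifies)),
                         !.data$any_gs)
  if (nrow(empty)) {
    abort(paste0("no growing season (no month with mean daily temperature ",
                 "> 0 C) at site(s): ",
                 paste(empty$site_id, collapse = ", ")))
  }
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(m, .data$qualifies), .data$site_id),
    tg_c = mean(.data$tg_month),
    ppfd = mean(.data$ppfd),
    d_kpa = pmax(mean(.data$d_month), d_floor_kpa),
    patm_pa = .data$patm_pa[1],
    n_months_used = dplyr::n(),
    .groups = "drop"
  )
  out
}
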