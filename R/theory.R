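#' Arrhenius temperature scaling of a kinetic rate
#'
#' Scales a rate known at the 25 degree C reference temperature to another
#' temperature using the Arrhenius equation,
#' `rate(T) = rate25 * exp[(dHa/R) * (1/298.15 - 1/(T + 273.15))]`,
#' with R = 8.314 J/mol/K.
#'
#' @param rate25 Rate at 25 degrees C; must be positive.
#' @param dha Activation energy, J/mol.
#' @param t_c Target temperature, degrees C (> -273.15).
#' @return The rate at `t_c`, same units as `rate25`.
#' @examples
#' arrhenius_scale(50, 65330, 25) # identity at the reference temperature
#' arrhenius_scale(1, 79430, 35)
#' @export
arrhenius_scale <- function(rate25, dha, t_c) {
  if (!all(is.finite(rate25)) || !all(is.finite(dha)) || !all(is.finite(t_c))) {
    abort("`rate25`, `dha` and `t_c` must be finite")
  }
  if (any(rate25 <= 0)) abort("`rate25` must be positive")
  if (any(t_c <= -273.15)) abort("`t_c` must be above absolute zero")
  rate25 * arrhenius_factor(dha, t_c)
}

# bare exp factor, shared by standardization code (which divides by it)
arrhenius_factor <- function(dha, t_c) {
  exp(dha / .R_GAS * (1 / .T_REF_K - 1 / (t_c + 273.15)))
}

#' Photorespiratory compensation point
#'
#' The CO2 compensation point of photosynthesis in the absence of day
#' respiration, Arrhenius-scaled to temperature and rescaled in direct
#' proportion to atmospheric pressure (it is a partial pressure tied to a
#' mole fraction).
#'
#' @param t_c Temperature, degrees C.
#' @param patm Atmospheric pressure, Pa.
#' @param params A [kinetic_params()] set.
#' @return Compensation point, Pa.
#' @examples
#' gamma_star(25, 101325) # the 25 C sea-level constant itself
#' @export
gamma_star <- function(t_c, patm = .PATM0, params = kinetic_params()) {
  if (any(!is.finite(patm)) || any(patm <= 0)) abort("`patm` must be positive")
  arrhenius_scale(params$gammastar25, params$dha_gammastar, t_c) *
    (patm / .PATM0)
}

#' Effective Michaelis-Menten coefficient of Rubisco
#'
#' Combines the CO2 and O2 affinities as `K = Kc * (1 + O/Ko)`, with Kc and
#' Ko Arrhenius-scaled to temperature and the O2 partial pressure
#' proportional to atmospheric pressure.
#'
#' @inheritParams gamma_star
#' @return Effective coefficient K, Pa.
#' @examples
#' michaelis_k(25, 101325)
#' @export
michaelis_k <- function(t_c, patm = .PATM0, params = kinetic_params()) {
  if (any(!is.finite(patm)) || any(patm <= 0)) abort("`patm` must be positive")
  kc <- arrhenius_scale(params$kc25, params$dha_kc, t_c) * (patm / .PATM0)
  ko <- arrhenius_scale(params$ko25, params$dha_ko, t_c) * (patm / .PATM0)
  o <- params$o2_frac * patm
  kc * (1 + o / ko)
}

#' Relative viscosity of water
#'
#' Dynamic viscosity of liquid water at `t_c` relative to its value at
#' 25 degrees C, from the Vogel-type correlation
#' `eta(T) = 2.414e-5 * 10^(247.8 / (T_K - 140))` Pa s. The correlation is
#' encapsulated here so that a different published form can be substituted
#' without touching the optimality equations.
#'
#' @param t_c Temperature, degrees C; valid for liquid water, 0-60.
#' @return Dimensionless ratio, 1 at 25 degrees C, decreasing with
#'   temperature.
#' @examples
#' eta_star(25)
#' eta_star(10)
#' @export
eta_star <- function(t_c) {
  if (any(!is.finite(t_c))) abort("`t_c` must be finite")
  if (any(t_c < 0 | t_c > 60)) {
    abort("`t_c` outside the 0-60 C validity range of the viscosity correlation")
  }
  visc <- function(t) 2.414e-5 * 10^(247.8 / (t + 273.15 - 140))
  visc(t_c) / visc(25)
}

#' Intrinsic quantum efficiency of photosynthesis
#'
#' Temperature response of the intrinsic quantum efficiency,
#' `phi0 = (c0 + c1*Tg + c2*Tg^2) / 8`, following the temperature dependence
#' of electron transport in light-adapted leaves.
#'
#' @param tg_c Daytime growth temperature, degrees C.
#' @inheritParams gamma_star
#' @return phi0, mol C per mol photons.
#' @examples
#' phi0_temperature(25)
#' @export
phi0_temperature <- function(tg_c, params = kinetic_params()) {
  cf <- params$phi0_coeffs
  val <- (cf[1] + cf[2] * tg_c + cf[3] * tg_c^2) / 8
  if (any(val <= 0)) {
    abort("quantum-efficiency polynomial is non-positive at the requested temperature")
  }
  val
}

# Internal scalar/vector core of the optimality chain. All pressures in Pa,
# D in Pa. Returns a list of the intermediate quantities.
optimality_chain <- function(ppfd, tg_c, d_pa, patm, ca_ppm, params,
                             include_phi0 = TRUE) {
  if (any(!is.finite(ppfd)) || any(ppfd < 0)) abort("`ppfd` must be >= 0")
  if (any(!is.finite(d_pa)) || any(d_pa < 0)) abort("vapour pressure deficit must be >= 0")
  if (any(!is.finite(patm)) || any(patm <= 0)) abort("`patm` must be positive")
  if (any(!is.finite(tg_c)) || any(tg_c <= -25) || any(tg_c >= 60)) {
    abort("`tg_c` must lie in (-25, 60)")
  }
  gs <- gamma_star(tg_c, patm, params)
  k <- michaelis_k(tg_c, patm, params)
  ca <- ca_ppm * 1e-6 * patm
  if (any(ca <= gs)) {
    abort("ambient CO2 partial pressure at or below the compensation point: degenerate environment")
  }
  es <- eta_star(tg_c)
  xi <- sqrt(params$beta * (k + gs) / (1.6 * es))
  g <- gs / ca
  chi <- g + (1 - g) * xi / (xi + sqrt(d_pa))
  ci <- chi * ca
  phi0 <- if (include_phi0) phi0_temperature(tg_c, params) else
    phi0_temperature(25, params)
  vcmax <- phi0 * ppfd * (ci + k) / (ci + 2 * gs)
  vcmax25 <- vcmax / arrhenius_factor(params$dha_vcmax, tg_c)
  list(gammastar = gs, k = k, ca = ca, eta_star = es, xi = xi, chi = chi,
       ci = ci, phi0 = phi0, vcmax = vcmax, vcmax25 = vcmax25)
}

resolve_patm <- function(data) {
  if ("patm_pa" %in% names(data)) return(data[["patm_pa"]])
  z <- if ("elevation_m" %in% names(data)) data[["elevation_m"]] else 0
  patm_from_elevation(z)
}

#' Optimal ci/ca ratio under the least-cost hypothesis
#'
#' For each environment row, computes the ci/ca ratio chi that minimizes the
#' combined unit costs of maintaining transpiration and carboxylation
#' capacity:
#' `chi = gammastar/ca + (1 - gammastar/ca) * xi / (xi + sqrt(D))`, with
#' `xi = sqrt(beta * (K + gammastar) / (1.6 * eta_star))` and D in Pa.
#'
#' @param data Data frame with columns `tg_c` (daytime growth temperature,
#'   degrees C), `d_kpa` (vapour pressure deficit, kPa) and either
#'   `elevation_m` or `patm_pa` (defaults to sea level when both absent).
#' @param params A [kinetic_params()] set.
#' @param ca_ppm Ambient CO2 mole fraction, umol/mol; converted to a partial
#'   pressure with the row's atmospheric pressure.
#' @return The input as a tibble with columns `chi`, `ci_pa`, `xi`,
#'   `gammastar_pa`, `k_pa` and `eta_star` appended.
#' @examples
#' optimal_chi(data.frame(tg_c = 25, d_kpa = 0.6))
#' @export
optimal_chi <- function(data, params = kinetic_params(), ca_ppm = 400) {
  patm <- resolve_patm(data)
  ch <- optimality_chain(ppfd = rep(1, nrow(data)), tg_c = data$tg_c,
                         d_pa = data$d_kpa * 1000, patm = patm,
                         ca_ppm = ca_ppm, params = params)
  dplyr::mutate(as_tibble(data), chi = ch$chi, ci_pa = ch$ci, xi = ch$xi,
                gammastar_pa = ch$gammastar, k_pa = ch$k,
                eta_star = ch$eta_star)
}

#' Predict optimal photosynthetic capacity from climate
#'
#' The coordination hypothesis: under typical daytime growth conditions,
#' Rubisco carboxylation and electron transport are co-limiting, so the
#' optimal capacity is
#' `Vcmax = phi0(Tg) * PPFD * (ci + K) / (ci + 2*gammastar)`, with ci from
#' the least-cost chi ([optimal_chi()]). The result is standardized to
#' 25 degrees C by dividing by the Arrhenius factor for Vcmax at Tg.
#'
#' @param data Data frame with columns `ppfd` (umol/m2/s), `tg_c` (degrees
#'   C), `d_kpa` (kPa) and optionally `elevation_m` or `patm_pa`.
#' @inheritParams optimal_chi
#' @return The input as a tibble with `chi`, `ci_pa`, `gammastar_pa`, `k_pa`,
#'   `phi0`, `vcmax` (at Tg) and `vcmax25` (at 25 C), both umol/m2/s,
#'   appended.
#' @examples
#' predict_vcmax(data.frame(ppfd = 400, tg_c = 25, d_kpa = 0.6))
#' @export
predict_vcmax <- function(data, params = kinetic_params(), ca_ppm = 400) {
  patm <- resolve_patm(data)
  ch <- optimality_chain(ppfd = data$ppfd, tg_c = data$tg_c,
                         d_pa = data$d_kpa * 1000, patm = patm,
                         ca_ppm = ca_ppm, params = params)
  dplyr::mutate(as_tibble(data), chi = ch$chi, ci_pa = ch$ci,
                gammastar_pa = ch$gammastar, k_pa = ch$k, phi0 = ch$phi0,
                vcmax = ch$vcmax, vcmax25 = ch$vcmax25)
}

#' Climate elasticities of predicted ln Vcmax25
#'
#' Partial derivatives of ln Vcmax25 with respect to ln PPFD
#' (dimensionless), growth temperature Tg (per K) and ln D (dimensionless),
#' evaluated by central finite differences of the full optimality chain at
#' each environment row. Because predicted Vcmax25 is exactly proportional
#' to PPFD, the PPFD elasticity is 1 up to round-off.
#'
#' Whether the temperature dependence of the quantum efficiency phi0 is
#' carried through the Tg derivative is controlled by `include_phi0`; the
#' default excludes it, which is the variant consistent with the published
#' theoretical temperature coefficient (see the methods vignette). The
#' prediction itself ([predict_vcmax()]) always uses phi0 at Tg.
#'
#' @inheritParams predict_vcmax
#' @param include_phi0 Logical: carry phi0's temperature dependence through
#'   the Tg derivative?
#' @param rel_step Relative step for the log-scale differences (<= 1e-4).
#' @param tg_step Absolute step for the Tg difference, K (<= 0.01).
#' @return Tibble with one row per environment: `elast_ln_ppfd`, `elast_tg`,
#'   `elast_ln_d`.
#' @examples
#' climate_elasticities(data.frame(ppfd = 400, tg_c = 25, d_kpa = 0.6))
#' @export
climate_elasticities <- function(data, params = kinetic_params(),
                                 ca_ppm = 400, include_phi0 = FALSE,
                                 rel_step = 1e-5, tg_step = 0.01) {
  if (rel_step > 1e-4) abort("`rel_step` must be <= 1e-4")
  if (tg_step > 0.01) abort("`tg_step` must be <= 0.01 K")
  if (any(data$ppfd <= 0) || any(data$d_kpa <= 0)) {
    abort("elasticities require strictly interior environments (PPFD, D > 0)")
  }
  patm <- resolve_patm(data)
  lnv <- function(ppfd, tg, d_kpa) {
    log(optimality_chain(ppfd, tg, d_kpa * 1000, patm, ca_ppm, params,
                         include_phi0 = include_phi0)$vcmax25)
  }
  # central difference with step halving when an evaluation point leaves the
  # validity domain of the chain (e.g. the viscosity correlation)
  central <- function(f, h0) {
    h <- h0
    for (i in 1:10) {
      out <- tryCatch(f(h), error = function(e) NULL)
      if (!is.null(out)) return(out)
      h <- h / 2
    }
    abort("finite-difference step could not be placed inside the validity domain")
  }
  e_ppfd <- central(function(h) {
    (lnv(data$ppfd * exp(h), data$tg_c, data$d_kpa) -
       lnv(data$ppfd * exp(-h), data$tg_c, data$d_kpa)) / (2 * h)
  }, rel_step)
  e_tg <- central(function(h) {
    (lnv(data$ppfd, data$tg_c + h, data$d_kpa) -
       lnv(data$ppfd, data$tg_c - h, data$d_kpa)) / (2 * h)
  }, tg_step)
  e_d <- central(function(h) {
    (lnv(data$ppfd, data$tg_c, data$d_kpa * exp(h)) -
       lnv(data$ppfd, data$tg_c, data$d_kpa * exp(-h))) / (2 * h)
  }, rel_step)
  tibble(elast_ln_ppfd = e_ppfd, elast_tg = e_tg, elast_ln_d = e_d)
}
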