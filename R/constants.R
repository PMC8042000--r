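#' Enzyme-kinetic and cost constants for the optimality model
#'
#' Bundles the constants needed by the least-cost and coordination
#' calculations: Rubisco kinetics at 25 degrees C with their activation
#' energies (in vivo tobacco values), the unit-cost ratio beta of maintaining
#' carboxylation versus transpiration capacity, the quadratic temperature
#' response of the intrinsic quantum efficiency phi0, the day-respiration
#' fraction used by the one-point method, and the shortwave-to-photon-flux
#' conversion factor.
#'
#' The kinetic constants at 25 degrees C are stored as partial pressures (Pa)
#' at sea-level standard pressure; they are rescaled in direct proportion to
#' atmospheric pressure where pressure matters. All fields can be overridden,
#' which allows variant constant sets to be swapped in without touching any
#' downstream code.
#'
#' @param gammastar25 Photorespiratory CO2 compensation point at 25 degrees C
#'   and sea-level pressure, Pa (default 42.75 umol/mol at 101325 Pa).
#' @param kc25 Michaelis-Menten coefficient of Rubisco for CO2 at 25 degrees
#'   C, Pa (default 404.9 umol/mol at sea level).
#' @param ko25 Michaelis-Menten coefficient of Rubisco for O2 at 25 degrees
#'   C, Pa (default 278.4 mmol/mol at sea level).
#' @param dha_gammastar,dha_kc,dha_ko,dha_vcmax,dha_jmax Activation energies,
#'   J/mol.
#' @param beta Ratio of the unit costs of maintaining carboxylation and
#'   transpiration capacity at 25 degrees C, dimensionless.
#' @param phi0_coeffs Numeric length-3: coefficients (c0, c1, c2) of the
#'   quadratic c0 + c1*Tg + c2*Tg^2 whose value divided by 8 is the intrinsic
#'   quantum efficiency.
#' @param rd_frac Day respiration as a fraction of Vcmax, dimensionless.
#' @param e2f Energy-to-flux conversion factor from shortwave irradiance
#'   (W/m2) to photosynthetic photon flux density (umol/m2/s), umol/J.
#' @param o2_frac O2 mole fraction of dry air, mol/mol.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params()
#' p$beta
#' kinetic_params(beta = 200)$beta
#' @export
kinetic_params <- function(gammastar25 = 42.75e-6 * 101325,
                           kc25 = 404.9e-6 * 101325,
                           ko25 = 278.4e-3 * 101325,
                           dha_gammastar = 37830,
                           dha_kc = 79430,
                           dha_ko = 36380,
                           dha_vcmax = 65330,
                           dha_jmax = 43900,
                           beta = 146,
                           phi0_coeffs = c(0.352, 0.021, -3.4e-4),
                           rd_frac = 0.015,
                           e2f = 2.04,
                           o2_frac = 0.2095) {
  p <- list(
    gammastar25 = gammastar25, kc25 = kc25, ko25 = ko25,
    dha_gammastar = dha_gammastar, dha_kc = dha_kc, dha_ko = dha_ko,
    dha_vcmax = dha_vcmax, dha_jmax = dha_jmax,
    beta = beta, phi0_coeffs = phi0_coeffs,
    rd_frac = rd_frac, e2f = e2f, o2_frac = o2_frac
  )
  scalars <- p[setdiff(names(p), "phi0_coeffs")]
  if (!all(vapply(scalars, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    abort("all kinetic parameters must be finite numeric scalars")
  }
  positive <- c("gammastar25", "kc25", "ko25", "dha_gammastar", "dha_kc",
                "dha_ko", "dha_vcmax", "dha_jmax", "beta", "rd_frac", "e2f")
  bad <- positive[vapply(p[positive], function(x) x <= 0, logical(1))]
  if (length(bad)) {
    abort(paste0("kinetic parameters must be positive: ",
                 paste(bad, collapse = ", ")))
  }
  if (length(p$phi0_coeffs) != 3 || !all(is.finite(p$phi0_coeffs))) {
    abort("`phi0_coeffs` must be three finite coefficients")
  }
  if (p$o2_frac < 0) abort("`o2_frac` must be non-negative")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  gammastar25 %.4f Pa | kc25 %.3f Pa | ko25 %.1f Pa\n",
              x$gammastar25, x$kc25, x$ko25))
  cat(sprintf("  dHa (J/mol): gammastar %g, kc %g, ko %g, vcmax %g, jmax %g\n",
              x$dha_gammastar, x$dha_kc, x$dha_ko, x$dha_vcmax, x$dha_jmax))
  cat(sprintf("  beta %g | rd_frac %g | e2f %g umol/J | O2 %g mol/mol\n",
              x$beta, x$rd_frac, x$e2f, x$o2_frac))
  cat(sprintf("  phi0 = (%g + %g Tg %+g Tg^2)/8\n",
              x$phi0_coeffs[1], x$phi0_coeffs[2], x$phi0_coeffs[3]))
  invisible(x)
}
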