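#' One-point estimate of Vcmax from light-saturated assimilation
#'
#' Estimates the maximum carboxylation rate at leaf temperature from a
#' single light-saturated net assimilation measurement:
#' `Vcmax = (Asat + Rd) * (ci + K) / (ci - gammastar)`, with K and gammastar
#' evaluated at the leaf temperature and atmospheric pressure.
#'
#' @param asat Light-saturated net assimilation, umol/m2/s (> 0).
#' @param rd Day respiration, umol/m2/s (>= 0).
#' @param ci_pa Intercellular CO2 partial pressure, Pa; must exceed the
#'   compensation point.
#' @param t_leaf_c Leaf temperature, degrees C.
#' @param patm Atmospheric pressure, Pa.
#' @param params A [kinetic_params()] set.
#' @return Vcmax at `t_leaf_c`, umol/m2/s.
#' @examples
#' vcmax_one_point(asat = 20, rd = 1, ci_pa = 25, t_leaf_c = 25)
#' @export
vcmax_one_point <- function(asat, rd, ci_pa, t_leaf_c, patm = .PATM0,
                            params = kinetic_params()) {
  if (any(asat <= 0)) abort("`asat` must be positive")
  if (any(rd < 0)) abort("`rd` must be non-negative")
  gs <- gamma_star(t_leaf_c, patm, params)
  if (any(ci_pa <= gs)) {
    abort("`ci_pa` at or below the compensation point: Vcmax is undefined")
  }
  k <- michaelis_k(t_leaf_c, patm, params)
  (asat + rd) * (ci_pa + k) / (ci_pa - gs)
}

#' One-point Vcmax estimate without a respiration measurement
#'
#' When day respiration is not measured it is assumed to be a fixed fraction
#' (default 1.5%) of Vcmax, giving
#' `Vcmax = Asat / [(ci - gammastar)/(ci + K) - rd_frac]`.
#'
#' @inheritParams vcmax_one_point
#' @return Vcmax at `t_leaf_c`, umol/m2/s.
#' @examples
#' vcmax_one_point_no_rd(asat = 20, ci_pa = 25, t_leaf_c = 25)
#' @export
vcmax_one_point_no_rd <- function(asat, ci_pa, t_leaf_c, patm = .PATM0,
                                  params = kinetic_params()) {
  if (any(asat <= 0)) abort("`asat` must be positive")
  gs <- gamma_star(t_leaf_c, patm, params)
  k <- michaelis_k(t_leaf_c, patm, params)
  denom <- (ci_pa - gs) / (ci_pa + k) - params$rd_frac
  if (any(denom <= 0)) {
    abort("assumed respiration exceeds gross assimilation: one-point estimate undefined")
  }
  asat / denom
}

#' Standardize a kinetic rate to 25 degrees C
#'
#' Divides a rate measured at leaf temperature by the Arrhenius factor for
#' the chosen quantity, returning the rate at the 25 degree C reference.
#'
#' @param v Rate at `t_c`, umol/m2/s.
#' @param t_c Measurement temperature, degrees C, in \[0, 50\].
#' @param which `"vcmax"` or `"jmax"` (selects the activation energy).
#' @param params A [kinetic_params()] set.
#' @return Rate at 25 degrees C.
#' @examples
#' standardize_to_25(100, 30)
#' @export
standardize_to_25 <- function(v, t_c, which = c("vcmax", "jmax"),
                              params = kinetic_params()) {
  which <- match.arg(which)
  if (any(!is.finite(t_c)) || any(t_c < 0 | t_c > 50)) {
    abort("`t_c` must lie in [0, 50] C")
  }
  dha <- if (which == "vcmax") params$dha_vcmax else params$dha_jmax
  v / arrhenius_factor(dha, t_c)
}

#' Aggregate leaf records to site means
#'
#' Builds the site-mean analysis table. By default averaging is two-stage,
#' matching the definition of the analysis data points: individuals are
#' first averaged within species at a site, then species averages are
#' averaged to a site mean. Means are taken on the natural scale over
#' non-missing values only (log-transformation, where wanted, happens at
#' regression time). Optional soil properties are joined by `site_id`; soil
#' rows without a matching site are dropped with a warning.
#'
#' @param records Data frame of leaf records with columns `site_id`,
#'   `species`, `vcmax25` and optionally `jmax25`, `narea`, `parea`.
#' @param soil Optional data frame with columns `site_id`, `ph`, `c_to_n`,
#'   `total_p`.
#' @param two_stage Average individuals to species-at-site first (default)?
#'   `FALSE` pools all records at a site directly.
#' @return Tibble with one row per site: trait means, `n_species`,
#'   `n_records`, per-trait counts `n_<trait>`, and soil columns when
#'   supplied.
#' @examples
#' rec <- tibble::tibble(site_id = "a", species = c("x", "y"),
#'                       vcmax25 = c(40, 60))
#' aggregate_site_means(rec)
#' @export
aggregate_site_means <- function(records, soil = NULL, two_stage = TRUE) {
  if (nrow(records) == 0) abort("`records` is empty")
  traits <- intersect(c("vcmax25", "jmax25", "narea", "parea"),
                      names(records))
  if (!"vcmax25" %in% traits) abort("`records` must contain `vcmax25`")
  base <- as_tibble(records)
  if (two_stage) {
    base <- dplyr::summarise(
      dplyr::group_by(base, .data$site_id, .data$species),
      dplyr::across(dplyr::all_of(traits), ~ mean(.x, na.rm = TRUE)),
      n_records = dplyr::n(), .groups = "drop"
    )
  } else {
    base$n_records <- 1L
  }
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  out <- dplyr::summarise(
    dplyr::group_by(base, .data$site_id),
    dplyr::across(dplyr::all_of(traits), ~ sum(!is.na(.x)),
                  .names = "n_{.col}"),
    dplyr::across(dplyr::all_of(traits), mean_na),
    n_species = dplyr::n_distinct(.data$species),
    n_records = sum(.data$n_records),
    .groups = "drop"
  )
  if (!is.null(soil)) {
    orphans <- setdiff(soil$site_id, out$site_id)
    if (length(orphans)) {
      warn(sprintf("%d soil row(s) without matching leaf records dropped",
                   length(orphans)))
    }
    out <- dplyr::left_join(out, as_tibble(soil), by = "site_id")
  }
  out
}

#' Convert leaf nutrient contents between mass and molar area bases
#'
#' Leaf N and P per area are carried as g/m2 throughout; these helpers
#' convert to and from mmol/m2 using the atomic masses of N (14.007 g/mol)
#' and P (30.974 g/mol).
#'
#' @param x Nutrient content (g/m2 for `*_to_mmol`, mmol/m2 for
#'   `*_from_mmol`).
#' @param element `"N"` or `"P"`.
#' @return Converted content.
#' @examples
#' nutrient_to_mmol(1.4, "N")
#' @export
nutrient_to_mmol <- function(x, element = c("N", "P")) {
  element <- match.arg(element)
  x / c(N = 14.007, P = 30.974)[[element]] * 1000
}

#' @rdname nutrient_to_mmol
#' @export
nutrient_from_mmol <- function(x, element = c("N", "P")) {
  element <- match.arg(element)
  x * c(N = 14.007, P = 30.974)[[element]] / 1000
}
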