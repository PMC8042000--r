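# Seeded synthetic leaf-trait generator. Emulates the statistical structure
# the analysis pipeline assumes: per-site growing-season climate, theory-
# driven ln Vcmax25 with crossed site/species random intercepts, leaf N
# coupled to photosynthetic capacity, leaf P coupled to soil P, and monthly
# climate tables that aggregate back to the generating drivers exactly.

#' Configuration for the synthetic leaf-trait generator
#'
#' All knobs of [generate_dataset()] in one validated list. Defaults emulate
#' a global unfertilized-vegetation compilation: a few hundred sites spanning
#' wide climate gradients, several species per site drawn from a shared pool
#' (so species recur across sites and the site/species design is crossed),
#' and log-scale noise split so that site identity carries 50%, species
#' identity 22% and the residual 28% of the variation unexplained by
#' climate.
#'
#' @param seed Integer seed; mandatory, every draw is derived from it.
#' @param n_sites Number of sites.
#' @param species_per_site Species sampled per site from the shared pool.
#' @param ppfd_range Growing-season PPFD range, umol/m2/s (log-uniform).
#' @param tg_range Daytime growth temperature range, degrees C (uniform).
#' @param d_range Vapour pressure deficit range, kPa (log-uniform; capped at
#'   80% of saturation at the site's diurnal mean temperature so the monthly
#'   humidity inversion stays physical).
#' @param elev_range Elevation range, m (uniform).
#' @param sigma_site,sigma_species,sigma_resid Standard deviations of the
#'   site, species and residual Gaussian effects on ln Vcmax25.
#' @param theory_mode `"full"` evaluates the optimality chain
#'   ([predict_vcmax()]) at each site's climate; `"linearized"` uses the
#'   tangent plane of ln Vcmax25 at the median climate (PPFD 400, Tg 25 C,
#'   D 0.6 kPa, sea level), i.e. an exactly linear surface in (ln PPFD, Tg,
#'   ln D) with the theoretical elasticities as coefficients.
#' @param ca_ppm Ambient CO2 mole fraction for the theory evaluation.
#' @param narea_intercept,narea_slope Structural intercept (g/m2) and
#'   metabolic slope (g/m2 per umol/m2/s) linking leaf N per area to
#'   Vcmax25.
#' @param narea_ph_slope Additional dependence of Narea on soil pH
#'   (g/m2 per pH unit, centred at pH 6; negative by default).
#' @param narea_sd Gaussian noise on Narea, g/m2.
#' @param parea_log_intercept,parea_log_slope Regression of ln Parea (g/m2)
#'   on ln soil total P.
#' @param parea_log_sd Log-scale noise on Parea.
#' @param ph_range,c_to_n_range,total_p_range Soil property ranges (pH
#'   units, dimensionless, mg/kg), drawn uniformly per site.
#' @param p_cap Apply a phosphorus limitation cap to ln Vcmax25?
#' @param cap_intercept,cap_slope P-limitation limb: the cap on ln Vcmax25
#'   is `cap_intercept + cap_slope * ln(Parea)`.
#' @param cap_k Sharpness of the smooth minimum implementing the cap.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(seed,
                             n_sites = 200,
                             species_per_site = 8,
                             ppfd_range = c(100, 800),
                             tg_range = c(0, 30),
                             d_range = c(0.1, 3),
                             elev_range = c(0, 4500),
                             sigma_site = sqrt(0.50 * 0.8),
                             sigma_species = sqrt(0.22 * 0.8),
                             sigma_resid = sqrt(0.28 * 0.8),
                             theory_mode = c("full", "linearized"),
                             ca_ppm = 400,
                             narea_intercept = 0.6,
                             narea_slope = 0.008,
                             narea_ph_slope = -0.25,
                             narea_sd = 0.15,
                             parea_log_intercept = -5.4,
                             parea_log_slope = 0.5,
                             parea_log_sd = 0.3,
                             ph_range = c(3.5, 8.5),
                             c_to_n_range = c(5, 40),
                             total_p_range = c(50, 1500),
                             p_cap = FALSE,
                             cap_intercept = 5.4,
                             cap_slope = 0.7,
                             cap_k = 50) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number")
  }
  theory_mode <- match.arg(theory_mode)
  ranges <- list(ppfd_range = ppfd_range, tg_range = tg_range,
                 d_range = d_range, elev_range = elev_range,
                 ph_range = ph_range, c_to_n_range = c_to_n_range,
                 total_p_range = total_p_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      abort(paste0("`", nm, "` must be an ordered length-2 range"))
    }
  }
  if (any(c(sigma_site, sigma_species, sigma_resid, narea_sd,
            parea_log_sd) < 0)) {
    abort("noise standard deviations must be non-negative")
  }
  if (n_sites < 1 || species_per_site < 1) {
    abort("`n_sites` and `species_per_site` must be at least 1")
  }
  cfg <- c(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                species_per_site = as.integer(species_per_site),
                theory_mode = theory_mode, ca_ppm = ca_ppm,
                sigma_site = sigma_site, sigma_species = sigma_species,
                sigma_resid = sigma_resid,
                narea_intercept = narea_intercept, narea_slope = narea_slope,
                narea_ph_slope = narea_ph_slope, narea_sd = narea_sd,
                parea_log_intercept = parea_log_intercept,
                parea_log_slope = parea_log_slope,
                parea_log_sd = parea_log_sd,
                p_cap = p_cap, cap_intercept = cap_intercept,
                cap_slope = cap_slope, cap_k = cap_k),
           ranges)
  structure(cfg, class = "generator_config")
}

#' Configured variance fractions of a generator configuration
#'
#' The shares of the climate-unexplained ln Vcmax25 variance assigned to
#' site, species and residual effects; the quantities the crossed mixed
#' model ([fit_all_species()]) is expected to recover.
#'
#' @param config A [generator_config()].
#' @return Named numeric vector (`site`, `species`, `residual`).
#' @export
config_variance_fractions <- function(config) {
  v <- c(site = config$sigma_site^2, species = config$sigma_species^2,
         residual = config$sigma_resid^2)
  v / sum(v)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])
runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

magnus_es <- function(t_c) 0.611 * exp(17.27 * t_c / (t_c + 237.3))

#' Generate a synthetic leaf-trait dataset
#'
#' Runs the generating pipeline: (1) draw site climates and soils; (2)
#' evaluate the optimality theory for ln Vcmax25 at each site's climate;
#' (3) add crossed Gaussian site, species and residual effects; (4)
#' optionally cap ln Vcmax25 by a phosphorus limb through a smooth minimum;
#' (5) derive leaf N per area from realized Vcmax25 (metabolic component)
#' plus a structural intercept and a soil-pH term; (6) derive leaf P per
#' area from soil total P; (7) emit a monthly climate table that aggregates
#' back to the generating growing-season drivers exactly (twelve identical
#' equatorial months whose daytime-temperature and humidity relations are
#' inverted analytically).
#'
#' All randomness derives from `config$seed` through fixed per-field
#' substreams, so identical configurations reproduce identical tables and
#' adding a downstream field never shifts earlier draws.
#'
#' @param config A [generator_config()].
#' @return An object of class `vcmax_sim`: a list with tibbles `leaf_obs`
#'   (site_id, species, vcmax25, narea, parea), `soil`, `climate_monthly`,
#'   `sites` (the generating growing-season climate per site) and `truth`
#'   (per record: theory value, effect draws and the true limitation label).
#' @examples
#' sim <- generate_dataset(generator_config(seed = 1, n_sites = 20,
#'                                          species_per_site = 3))
#' head(sim$leaf_obs)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ns <- config$n_sites
  sps <- config$species_per_site
  seed_for <- function(offset) set.seed(config$seed + offset)

  # (1) site climates and soils
  seed_for(1L)
  site_id <- sprintf("s%04d", seq_len(ns))
  ppfd <- runif_log(ns, config$ppfd_range)
  tg <- runif_range(ns, config$tg_range)
  elev <- runif_range(ns, config$elev_range)
  d_raw <- runif_log(ns, config$d_range)
  dtr <- pmin(10, 3 * tg)             # diurnal temperature range, degrees C
  tmean <- tg - dtr / pi              # diurnal mean behind the daytime mean
  d_kpa <- pmin(d_raw, 0.8 * magnus_es(tmean))
  patm <- patm_from_elevation(elev)
  sites <- tibble(site_id = site_id, lat = 0, elevation_m = elev,
                  ppfd = ppfd, tg_c = tg, d_kpa = d_kpa, patm_pa = patm)

  seed_for(2L)
  soil <- tibble(site_id = site_id,
                 ph = runif_range(ns, config$ph_range),
                 c_to_n = runif_range(ns, config$c_to_n_range),
                 total_p = runif_range(ns, config$total_p_range))

  # (2) theory surface
  if (config$theory_mode == "full") {
    ln_theory <- log(predict_vcmax(sites, ca_ppm = config$ca_ppm)$vcmax25)
  } else {
    med <- tibble(ppfd = 400, tg_c = 25, d_kpa = 0.6, elevation_m = 0)
    el <- climate_elasticities(med, ca_ppm = config$ca_ppm)
    ln_med <- log(predict_vcmax(med, ca_ppm = config$ca_ppm)$vcmax25)
    ln_theory <- ln_med + el$elast_ln_ppfd * (log(ppfd) - log(400)) +
      el$elast_tg * (tg - 25) + el$elast_ln_d * (log(d_kpa) - log(0.6))
  }

  # (3) crossed effects: species pool shared across sites
  n_pool <- max(2L, as.integer(round(ns * sps / 2)))
  pool <- sprintf("sp%05d", seq_len(n_pool))
  seed_for(3L)
  species <- unlist(lapply(seq_len(ns), function(i) {
    sample(pool, min(sps, n_pool), replace = FALSE)
  }))
  rec_site <- rep(seq_len(ns), each = min(sps, n_pool))
  n_rec <- length(species)

  seed_for(4L)
  site_eff <- stats::rnorm(ns, 0, config$sigma_site)
  seed_for(5L)
  species_eff <- setNames(stats::rnorm(n_pool, 0, config$sigma_species), pool)
  seed_for(6L)
  resid_eff <- stats::rnorm(n_rec, 0, config$sigma_resid)

  ln_v <- ln_theory[rec_site] + site_eff[rec_site] +
    unname(species_eff[species]) + resid_eff

  # (6, drawn before the cap needs it) leaf P from soil total P
  seed_for(7L)
  parea <- exp(config$parea_log_intercept +
                 config$parea_log_slope * log(soil$total_p[rec_site]) +
                 stats::rnorm(n_rec, 0, config$parea_log_sd))

  # (4) optional phosphorus limitation cap
  limitation <- rep("unlimited", n_rec)
  if (config$p_cap) {
    cap <- config$cap_intercept + config$cap_slope * log(parea)
    limitation <- ifelse(cap < ln_v, "P-limited", "N-limited")
    ln_v <- smooth_min(ln_v, cap, config$cap_k)
  }
  vcmax25 <- exp(ln_v)

  # (5) leaf N: metabolic component proportional to capacity, structural
  # intercept, and a soil-pH dependence of N availability
  seed_for(8L)
  narea <- pmax(0.15,
                config$narea_intercept + config$narea_slope * vcmax25 +
                  config$narea_ph_slope * (soil$ph[rec_site] - 6) +
                  stats::rnorm(n_rec, 0, config$narea_sd))

  leaf_obs <- tibble(site_id = site_id[rec_site], species = species,
                     vcmax25 = vcmax25, narea = narea, parea = parea)
  truth <- tibble(site_id = site_id[rec_site], species = species,
                  ln_vcmax25_theory = ln_theory[rec_site],
                  site_effect = site_eff[rec_site],
                  species_effect = unname(species_eff[species]),
                  residual = resid_eff, limitation = limitation)

  # (7) monthly climate inverting the growing-season aggregation: twelve
  # identical equatorial months (daylength weight exactly 1/2 + 1/pi)
  tmax <- tmean + dtr / 2
  tmin <- tmean - dtr / 2
  es <- magnus_es(tmean)
  ea_pa <- (es - d_kpa) * 1000
  rd <- .R_GAS / 0.028963
  rv <- .R_GAS / 0.01802
  wair <- ea_pa * rd / (rv * (patm - ea_pa))
  q_air <- wair / (1 + wair)
  climate_monthly <- tidyr::crossing(tibble(site_id = site_id), month = 1:12)
  climate_monthly <- dplyr::left_join(
    climate_monthly,
    tibble(site_id = site_id, lat = 0, elevation_m = elev, tmax_c = tmax,
           tmin_c = tmin, sw_wm2 = ppfd / kinetic_params()$e2f,
           q_air = q_air),
    by = "site_id"
  )
  structure(list(leaf_obs = leaf_obs, soil = soil,
                 climate_monthly = climate_monthly, sites = sites,
                 truth = truth, config = config),
            class = "vcmax_sim")
}

#' @export
print.vcmax_sim <- function(x, ...) {
  cat(sprintf("<vcmax_sim> %d sites, %d records, seed %d, theory %s%s\n",
              nrow(x$sites), nrow(x$leaf_obs), x$config$seed,
              x$config$theory_mode,
              if (x$config$p_cap) ", P cap on" else ""))
  invisible(x)
}

#' Record-level analysis table of a simulation
#'
#' Joins the leaf observations with their site's growing-season climate,
#' yielding the table [fit_all_species()] and the bias pipeline expect.
#'
#' @param sim A `vcmax_sim` from [generate_dataset()].
#' @return Tibble with one row per leaf record including climate columns.
#' @export
sim_analysis_table <- function(sim) {
  stopifnot(inherits(sim, "vcmax_sim"))
  dplyr::left_join(sim$leaf_obs, sim$sites, by = "site_id")
}

#' Small deterministic fixtures
#'
#' Hand-checkable tables used in examples and tests: `"tiny"` is a 3-site,
#' 2-species leaf table with soil; `"table1_median"` is the single reference
#' environment at the median climate of the global dataset (PPFD 400
#' umol/m2/s, Tg 25 C, D 0.6 kPa, sea level); `"minfunc_demo"` is 40
#' records lying exactly on the hard minimum of two known nutrient limbs
#' (ln Vcmax25 = min(3.2 + 0.8 ln Narea, 4.9 + 0.7 ln Parea)).
#'
#' @param name One of `"tiny"`, `"table1_median"`, `"minfunc_demo"`.
#' @return A tibble, or for `"tiny"` a list of tibbles.
#' @export
make_fixture <- function(name = c("tiny", "table1_median", "minfunc_demo")) {
  name <- match.arg(name)
  switch(name,
    tiny = list(
      leaf_obs = tibble(
        site_id = rep(c("a", "b", "c"), each = 2),
        species = rep(c("sp1", "sp2"), 3),
        vcmax25 = c(40, 60, 55, 45, 80, 70),
        narea = c(1.2, 1.8, 1.5, 1.4, 2.2, 2.0),
        parea = c(0.08, 0.12, 0.10, 0.09, 0.15, 0.14)
      ),
      soil = tibble(site_id = c("a", "b", "c"), ph = c(4.5, 6.0, 7.5),
                    c_to_n = c(25, 15, 10), total_p = c(200, 500, 900))
    ),
    table1_median = tibble(ppfd = 400, tg_c = 25, d_kpa = 0.6,
                           elevation_m = 0),
    minfunc_demo = {
      narea <- exp(seq(log(0.5), log(4), length.out = 40))
      # deterministic interleave so N and P gradients are not collinear
      parea <- exp(seq(log(0.02), log(0.4), length.out = 40))[
        c(rbind(seq(1, 39, 2), seq(40, 2, -2)))]
      ln_v <- pmin(3.2 + 0.8 * log(narea), 4.9 + 0.7 * log(parea))
      tibble(narea = narea, parea = parea, vcmax25 = exp(ln_v),
             true_limitation = ifelse(
               3.2 + 0.8 * log(narea) < 4.9 + 0.7 * log(parea),
               "N-limited", "P-limited"))
    }
  )
}
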