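# Independent oracles used across the suite. These re-derive quantities by
# closed forms or direct evaluation, separately from the package internals.

# Analytic (hand-derived) partial derivatives of ln Vcmax25 with respect to
# ln PPFD, Tg and ln D for the optimality chain. Serves as the symbolic-
# differentiation oracle against the package's central finite differences.
analytic_elasticities <- function(ppfd, tg, d_kpa, patm = 101325,
                                  ca_ppm = 400, include_phi0 = FALSE) {
  R <- 8.314
  p0 <- 101325
  tk <- tg + 273.15
  d <- d_kpa * 1000
  arr <- function(dh) exp(dh / R * (1 / 298.15 - 1 / tk))
  dln <- function(dh) dh / (R * tk^2) # d ln(arrhenius) / dT
  pr <- patm / p0
  gs <- 42.75e-6 * p0 * arr(37830) * pr
  kc <- 404.9e-6 * p0 * arr(79430) * pr
  ko <- 278.4e-3 * p0 * arr(36380) * pr
  o <- 0.2095 * patm
  K <- kc * (1 + o / ko)
  ca <- ca_ppm * 1e-6 * patm
  eta_rel <- 10^(247.8 / (tk - 140)) / 10^(247.8 / (298.15 - 140))
  xi <- sqrt(146 * (K + gs) / (1.6 * eta_rel))
  g <- gs / ca
  s <- xi / (xi + sqrt(d))
  chi <- g + (1 - g) * s
  ci <- chi * ca

  # ln D derivative: D enters only through chi
  dchi_dlnD <- -(1 - g) * xi * sqrt(d) / (2 * (xi + sqrt(d))^2)
  e_d <- (1 / (ci + K) - 1 / (ci + 2 * gs)) * ca * dchi_dlnD

  # Tg derivative: kinetics, viscosity, chi, Arrhenius standardization
  gs_p <- gs * dln(37830)
  kc_p <- kc * dln(79430)
  ko_p <- ko * dln(36380)
  K_p <- kc_p * (1 + o / ko) - kc * o * ko_p / ko^2
  eta_dln <- -log(10) * 247.8 / (tk - 140)^2
  xi_dln <- 0.5 * ((K_p + gs_p) / (K + gs) - eta_dln)
  s_p <- sqrt(d) * (xi * xi_dln) / (xi + sqrt(d))^2
  chi_p <- (gs_p / ca) * (1 - s) + (1 - g) * s_p
  ci_p <- ca * chi_p
  e_tg <- (ci_p + K_p) / (ci + K) - (ci_p + 2 * gs_p) / (ci + 2 * gs) -
    65330 / (R * tk^2)
  if (include_phi0) {
    e_tg <- e_tg + (0.021 + 2 * (-3.4e-4) * tg) /
      (0.352 + 0.021 * tg - 3.4e-4 * tg^2)
  }
  c(ln_ppfd = 1, tg = e_tg, ln_d = e_d)
}

# random interior environments for property tests
random_envs <- function(n) {
  tibble::tibble(
    ppfd = exp(stats::runif(n, log(100), log(800))),
    tg_c = stats::runif(n, 2, 38),
    d_kpa = exp(stats::runif(n, log(0.1), log(3))),
    elevation_m = stats::runif(n, 0, 3000)
  )
}

# nutrient records generated from two known limbs on the log scale
limb_records <- function(n, a_n = 3.2, b_n = 0.8, a_p = 4.9, b_p = 0.7,
                         k = Inf, noise_sd = 0, seed = NULL,
                         parea_meanlog = -2.6) {
  if (!is.null(seed)) set.seed(seed)
  narea <- exp(stats::rnorm(n, 0.4, 0.5))
  parea <- exp(stats::rnorm(n, parea_meanlog, 0.6))
  limb_n <- a_n + b_n * log(narea)
  limb_p <- a_p + b_p * log(parea)
  z <- if (is.finite(k)) {
    vcmaxopt::smooth_min(limb_n, limb_p, k)
  } else {
    pmin(limb_n, limb_p)
  }
  z <- z + stats::rnorm(n, 0, noise_sd)
  tibble::tibble(narea = narea, parea = parea, vcmax25 = exp(z),
                 true_limitation = ifelse(limb_n < limb_p,
                                          "N-limited", "P-limited"))
}
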