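test_that("Arrhenius scaling: identity at 25 C, round trip, hand-computed value", {
  expect_equal(arrhenius_scale(50, 65330, 25), 50)
  # round trip: scale to T, divide by the same factor
  scaled <- arrhenius_scale(37.2, 65330, 41)
  factor <- scaled / 37.2
  expect_equal(scaled / factor, 37.2, tolerance = 1e-14)
  # direct evaluation of the exponential, frozen independently
  expect_equal(arrhenius_scale(1, 79430, 35), 2.82883913107, tolerance = 1e-10)
  expect_error(arrhenius_scale(-1, 65330, 25), "positive")
  expect_error(arrhenius_scale(1, 65330, NA), "finite")
  # strictly increasing in T for positive activation energy
  tt <- seq(0, 40, by = 5)
  expect_true(all(diff(arrhenius_scale(1, 65330, tt)) > 0))
})

test_that("compensation point: identity, pressure proportionality, 35 C value", {
  p <- kinetic_params()
  expect_equal(gamma_star(25, 101325), p$gammastar25)
  expect_equal(gamma_star(25, 101325 / 2), p$gammastar25 / 2)
  expect_equal(gamma_star(35, 101325), 7.10787000087, tolerance = 1e-10)
  expect_error(gamma_star(25, -1), "positive")
})

test_that("effective Michaelis-Menten coefficient follows K = Kc (1 + O/Ko)", {
  # zero oxygen collapses K to Kc
  p0 <- kinetic_params(o2_frac = 0)
  expect_equal(michaelis_k(25, 101325, p0), p0$kc25)
  # K strictly increases with O at fixed temperature
  ks <- vapply(c(0.1, 0.2095, 0.3),
               function(f) michaelis_k(25, 101325, kinetic_params(o2_frac = f)),
               numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_gte(michaelis_k(25), kinetic_params()$kc25)
  # hand-evaluated with the shipped constants
  expect_equal(michaelis_k(25, 101325), 71.8995175673, tolerance = 1e-10)
})

test_that("relative water viscosity is 1 at 25 C, correct at 10 C, decreasing", {
  expect_equal(eta_star(25), 1)
  expect_equal(eta_star(10), 1.45943395485, tolerance = 1e-10)
  expect_true(eta_star(5) > eta_star(15) && eta_star(15) > eta_star(30))
  expect_error(eta_star(-5), "validity")
  expect_error(eta_star(70), "validity")
})

test_that("quantum efficiency quadratic: value, vertex, intercept", {
  expect_equal(phi0_temperature(25), 0.0830625)
  expect_equal(phi0_temperature(0), 0.352 / 8)
  # maximum at the vertex of the quadratic
  vertex <- 0.021 / (2 * 3.4e-4)
  expect_equal(vertex, 30.8823529412, tolerance = 1e-8)
  expect_gt(phi0_temperature(vertex), phi0_temperature(vertex - 3))
  expect_gt(phi0_temperature(vertex), phi0_temperature(vertex + 3))
  expect_error(phi0_temperature(-80, kinetic_params()), "non-positive")
})

test_that("optimal chi: limits in D, bounds, and climate monotonicity", {
  env <- function(d, tg = 25) data.frame(tg_c = tg, d_kpa = d)
  # D = 0 gives chi = 1 exactly
  expect_equal(optimal_chi(env(0))$chi, 1)
  # very large D approaches gammastar / ca
  big <- optimal_chi(env(1e9))
  expect_equal(big$chi, big$gammastar_pa / (400e-6 * 101325), tolerance = 1e-3)
  # median climate lands in the observed 0.5-0.9 range for C3 plants
  chi_med <- optimal_chi(data.frame(tg_c = 25, d_kpa = 0.6))$chi
  expect_gt(chi_med, 0.5)
  expect_lt(chi_med, 0.9)
  # bounds hold across random environments
  set.seed(11)
  ee <- random_envs(50)
  oc <- optimal_chi(ee)
  ca <- 400e-6 * patm_from_elevation(ee$elevation_m)
  expect_true(all(oc$chi <= 1 & oc$chi >= oc$gammastar_pa / ca))
  # decreasing in D, increasing in Tg on a grid
  dd <- optimal_chi(env(seq(0.1, 3, length.out = 10)))$chi
  expect_true(all(diff(dd) < 0))
  tt <- optimal_chi(data.frame(tg_c = seq(1, 40, length.out = 10), d_kpa = 0.8))$chi
  expect_true(all(diff(tt) > 0))
  expect_error(optimal_chi(data.frame(tg_c = 25, d_kpa = 0.6), ca_ppm = 30),
               "degenerate")
})

test_that("predicted Vcmax25 is proportional to PPFD and declines with Tg", {
  base <- data.frame(ppfd = 400, tg_c = 25, d_kpa = 0.6)
  v1 <- predict_vcmax(base)$vcmax25
  for (a in c(0.5, 2, 10)) {
    va <- predict_vcmax(transform(base, ppfd = 400 * a))$vcmax25
    expect_equal(va / v1, a, tolerance = 1e-12)
  }
  expect_equal(predict_vcmax(transform(base, ppfd = 0))$vcmax25, 0)
  v20 <- predict_vcmax(data.frame(ppfd = 400, tg_c = 20, d_kpa = 0.6))$vcmax25
  v30 <- predict_vcmax(data.frame(ppfd = 400, tg_c = 30, d_kpa = 0.6))$vcmax25
  expect_gt(v20, v30)
})

test_that("pressure consistency: elevation equals sea level with rescaled partial pressures", {
  z <- 2400
  patm_z <- patm_from_elevation(z)
  env_z <- data.frame(ppfd = 400, tg_c = 18, d_kpa = 0.9, elevation_m = z)
  at_z <- predict_vcmax(env_z)
  # computing at sea level after scaling every partial pressure (and the
  # kinetic constants, which are mole-fraction-tied) by patm(z)/patm(0)
  # must give the same prediction
  s <- patm_z / 101325
  p_scaled <- kinetic_params(gammastar25 = kinetic_params()$gammastar25 * s,
                             kc25 = kinetic_params()$kc25 * s,
                             ko25 = kinetic_params()$ko25 * s,
                             o2_frac = 0.2095 * s)
  env_0 <- data.frame(ppfd = 400, tg_c = 18, d_kpa = 0.9, elevation_m = 0)
  at_0 <- predict_vcmax(env_0, params = p_scaled, ca_ppm = 400 * s)
  expect_equal(at_z$vcmax25, at_0$vcmax25, tolerance = 1e-12)
  expect_equal(at_z$chi, at_0$chi, tolerance = 1e-12)
})

test_that("finite-difference elasticities match the analytic oracle", {
  set.seed(7)
  ee <- random_envs(20)
  got <- climate_elasticities(ee)
  for (i in seq_len(nrow(ee))) {
    want <- analytic_elasticities(ee$ppfd[i], ee$tg_c[i], ee$d_kpa[i],
                                  patm = patm_from_elevation(ee$elevation_m[i]))
    expect_equal(got$elast_ln_ppfd[i], want[["ln_ppfd"]], tolerance = 1e-6)
    expect_equal(got$elast_tg[i], want[["tg"]], tolerance = 1e-6)
    expect_equal(got$elast_ln_d[i], want[["ln_d"]], tolerance = 1e-6)
  }
  # and with the quantum-efficiency temperature term carried through
  got_p <- climate_elasticities(ee[1:5, ], include_phi0 = TRUE)
  for (i in 1:5) {
    want <- analytic_elasticities(ee$ppfd[i], ee$tg_c[i], ee$d_kpa[i],
                                  patm = patm_from_elevation(ee$elevation_m[i]),
                                  include_phi0 = TRUE)
    expect_equal(got_p$elast_tg[i], want[["tg"]], tolerance = 1e-6)
  }
})

test_that("PPFD elasticity is unity for any interior environment", {
  set.seed(21)
  ee <- random_envs(10)
  expect_equal(climate_elasticities(ee)$elast_ln_ppfd, rep(1, 10),
               tolerance = 1e-6)
  expect_error(climate_elasticities(data.frame(ppfd = 0, tg_c = 25, d_kpa = 0.6)),
               "interior")
})

test_that("kinetic parameter validation rejects bad inputs", {
  expect_error(kinetic_params(beta = -1), "positive")
  expect_error(kinetic_params(phi0_coeffs = c(1, 2)), "three")
  expect_s3_class(kinetic_params(beta = 200), "kinetic_params")
})
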