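make_linear_sites <- function(n, b = c(0.3, 1, -0.05, 0.07), noise = 0,
                              seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(
    ppfd = exp(runif(n, log(100), log(800))),
    tg_c = runif(n, 0, 30),
    d_kpa = exp(runif(n, log(0.1), log(3)))
  )
  lnv <- b[1] + b[2] * log(d$ppfd) + b[3] * d$tg_c + b[4] * log(d$d_kpa) +
    rnorm(n, 0, noise)
  dplyr::mutate(d, vcmax25 = exp(lnv))
}

test_that("site-mean OLS recovers an exactly linear log-scale surface", {
  d <- make_linear_sites(30)
  est <- suppressWarnings(tidy(fit_site_mean(d))$estimate)
  expect_equal(est, c(0.3, 1, -0.05, 0.07), tolerance = 1e-10)
  # degenerate sample size is refused
  expect_error(fit_site_mean(make_linear_sites(4)), "more sites")
  # collinear predictors are named
  dc <- make_linear_sites(20)
  dc$d_kpa <- dc$ppfd * 2
  expect_error(fit_site_mean(dc), "collinear|Collinear")
})

test_that("crossed mixed model collapses to OLS when random variance is zero", {
  cfg <- generator_config(seed = 4, n_sites = 25, species_per_site = 4,
                          sigma_site = 0, sigma_species = 0,
                          sigma_resid = 0.3)
  tab <- sim_analysis_table(generate_dataset(cfg))
  expect_warning(f <- fit_all_species(tab), "singular")
  expect_true(f$fallback)
  ols <- lm(log(vcmax25) ~ log(ppfd) + tg_c + log(d_kpa), data = tab)
  expect_equal(unname(tidy(f)$estimate), unname(coef(ols)), tolerance = 1e-6)
})

test_that("mixed model handles species shared across sites and reports variance shares", {
  cfg <- generator_config(seed = 8, n_sites = 60, species_per_site = 6)
  sim <- generate_dataset(cfg)
  tab <- sim_analysis_table(sim)
  # the pool is half the site-by-species slots, so species must recur
  expect_gt(max(table(unique(tab[c("site_id", "species")])$species)), 1)
  f <- fit_all_species(tab)
  vc <- variance_components(f)
  expect_setequal(vc$component, c("site_id", "species", "Residual"))
  expect_equal(sum(vc$fraction), 1, tolerance = 1e-12)
  expect_true(all(vc$fraction >= 0 & vc$fraction <= 1))
  g <- glance(f)
  expect_lt(g$r.squared.marginal, g$r.squared.conditional)
})

test_that("adding a truly present random term does not decrease the log-likelihood", {
  cfg <- generator_config(seed = 12, n_sites = 40, species_per_site = 5)
  tab <- sim_analysis_table(generate_dataset(cfg))
  full <- fit_all_species(tab)$fit
  reduced <- lme4::lmer(log(vcmax25) ~ log(ppfd) + tg_c + log(d_kpa) +
                          (1 | site_id), data = tab, REML = TRUE)
  expect_gte(as.numeric(logLik(full)), as.numeric(logLik(reduced)) - 1e-6)
})

test_that("bias statistic: exact formula and scale invariance", {
  expect_equal(bias(100, 100), 0)
  expect_equal(bias(110, 100), 10)
  expect_equal(bias(50, 100), -50)
  set.seed(2)
  pred <- runif(20, 10, 100)
  obs <- runif(20, 10, 100)
  expect_equal(bias(3.7 * pred, 3.7 * obs), bias(pred, obs),
               tolerance = 1e-12)
  expect_true(all(bias(runif(20, 1, 500), obs) > -100))
  expect_error(bias(10, 0), "positive")
})

test_that("theoretical prediction composes with the bias pipeline", {
  sim <- generate_dataset(generator_config(seed = 3, n_sites = 20,
                                           species_per_site = 3))
  tab <- theoretical_prediction(sim_analysis_table(sim))
  expect_true("vcmax25_pred" %in% names(tab))
  expect_equal(tab$vcmax25_pred,
               predict_vcmax(sim$sites)$vcmax25[
                 match(tab$site_id, sim$sites$site_id)])
  b <- bias(tab$vcmax25_pred, tab$vcmax25)
  expect_true(all(is.finite(b)))
})

test_that("bias regression: null covariates are not flagged, real signal is", {
  # type-I: bias independent of the nutrient covariates
  set.seed(31)
  null_cover <- replicate(100, {
    d <- tibble::tibble(narea = exp(rnorm(100, 0.4, 0.4)),
                        parea = exp(rnorm(100, -2.5, 0.5)),
                        bias = rnorm(100, 0, 20))
    td <- tidy(bias_regression(d, "nutrients"))
    sl <- td[td$term == "ln_parea", ]
    abs(sl$estimate) < 2 * sl$std.error
  })
  expect_gte(mean(null_cover), 0.90)
  # power: bias built from Parea is detected
  set.seed(32)
  hits <- replicate(50, {
    parea <- exp(rnorm(200, -2.5, 0.5))
    d <- tibble::tibble(narea = exp(rnorm(200, 0.4, 0.4)), parea = parea,
                        bias = 0.5 * (parea - mean(parea)) + rnorm(200, 0, 0.05))
    td <- tidy(bias_regression(d, "nutrients"))
    sl <- td[td$term == "ln_parea", ]
    sl$estimate > 0 && sl$p.value < 0.05
  })
  expect_gte(mean(hits), 0.90)
  # all-zero bias gives a zero slope exactly
  d0 <- tibble::tibble(narea = exp(rnorm(30, 0.4, 0.4)),
                       parea = exp(rnorm(30, -2.5, 0.5)), bias = 0)
  expect_equal(tidy(bias_regression(d0, "nutrients"))$estimate, rep(0, 3),
               tolerance = 1e-12)
})

test_that("partial residuals: slope identity and single-predictor degeneracy", {
  d <- make_linear_sites(40, noise = 0.3, seed = 9)
  f <- fit_site_mean(d)
  td <- tidy(f)
  for (p in f$predictors) {
    pr <- partial_residuals(f, p)
    slope <- coef(lm(partial_residual ~ x, data = pr))[2]
    expect_equal(unname(slope), td$estimate[td$term == p], tolerance = 1e-10)
  }
  expect_error(partial_residuals(f, "nosuch"), "unknown predictor")
  # single-predictor model: partial residuals are the observations
  one <- lm(z ~ x, data = data.frame(x = 1:10, z = log(2:11)))
  fv <- structure(list(fit = one, type = "ols", response = "z",
                       predictors = "x",
                       frame = data.frame(x = 1:10, z = log(2:11)),
                       fallback = FALSE), class = "vcmax_fit")
  pr1 <- partial_residuals(fv, "x")
  expect_equal(pr1$partial_residual, log(2:11), tolerance = 1e-12)
  # hand-computed 4-point example: y = 1 + 2x fitted exactly, residuals 0,
  # so partial residuals are intercept + slope * x
  d4 <- data.frame(x = c(0, 1, 2, 3), z = c(1, 3, 5, 7))
  f4 <- structure(list(fit = lm(z ~ x, data = d4), type = "ols",
                       response = "z", predictors = "x", frame = d4,
                       fallback = FALSE), class = "vcmax_fit")
  expect_equal(partial_residuals(f4, "x")$partial_residual, c(1, 3, 5, 7),
               tolerance = 1e-12)
})

test_that("OLS fits are invariant to row order and affine predictor scaling", {
  d <- make_linear_sites(35, noise = 0.2, seed = 14)
  f1 <- tidy(fit_site_mean(d))
  f2 <- tidy(fit_site_mean(d[sample(nrow(d)), ]))
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-12)
  # rescaling Tg by a factor rescales its coefficient inversely
  d_scaled <- dplyr::mutate(d, tg_c = tg_c * 2)
  f3 <- tidy(fit_site_mean(d_scaled))
  expect_equal(f3$estimate[f3$term == "tg_c"],
               f1$estimate[f1$term == "tg_c"] / 2, tolerance = 1e-10)
})

test_that("leaf-soil regressions recover the generating couplings", {
  # signs: Parea follows soil total P (+), Narea follows pH (-)
  set.seed(41)
  sign_ok <- replicate(20, {
    cfg <- generator_config(seed = sample.int(1e6, 1), n_sites = 120,
                            species_per_site = 6)
    sim <- generate_dataset(cfg)
    sm <- aggregate_site_means(sim$leaf_obs, sim$soil)
    fits <- leaf_soil_regressions(sm)
    tp <- tidy(fits$parea)
    tn <- tidy(fits$narea)
    c(p = tp$estimate[tp$term == "ln_total_p"] > 0,
      n = tn$estimate[tn$term == "ph"] < 0)
  })
  expect_gte(mean(sign_ok["p", ]), 0.95)
  expect_gte(mean(sign_ok["n", ]), 0.95)
  # decoupled generator: slopes not significant (type-I)
  set.seed(42)
  null_ok <- replicate(20, {
    cfg <- generator_config(seed = sample.int(1e6, 1), n_sites = 100,
                            species_per_site = 5, narea_ph_slope = 0,
                            parea_log_slope = 0)
    sim <- generate_dataset(cfg)
    sm <- aggregate_site_means(sim$leaf_obs, sim$soil)
    fits <- leaf_soil_regressions(sm)
    tp <- tidy(fits$parea)
    tn <- tidy(fits$narea)
    c(abs(tp$estimate[tp$term == "ln_total_p"]) <
        2 * tp$std.error[tp$term == "ln_total_p"],
      abs(tn$estimate[tn$term == "ph"]) < 2 * tn$std.error[tn$term == "ph"])
  })
  expect_gte(mean(null_ok), 0.85)
  # missing soil columns: informative skip
  sm_nosoil <- aggregate_site_means(make_fixture("tiny")$leaf_obs)
  expect_warning(out <- leaf_soil_regressions(sm_nosoil), "skip")
  expect_length(out, 0)
})

test_that("influence diagnostics rank points and support refitting", {
  d <- make_linear_sites(30, noise = 0.2, seed = 77)
  d$vcmax25[1] <- d$vcmax25[1] * 8 # gross outlier
  f <- fit_site_mean(d)
  diag <- influence_diagnostics(f)
  expect_equal(which.max(diag$cooks_d), 1L)
  f2 <- refit_without_influential(f, k = 1)
  expect_equal(nrow(f2$frame), 29)
  expect_lt(glance(f2)$sigma, glance(f)$sigma)
})
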