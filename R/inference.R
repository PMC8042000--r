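# Statistical layer: site-mean OLS and crossed-random-intercept mixed models
# of ln Vcmax25 on climate, the model-bias statistic, bias and leaf/soil
# regressions, and partial residuals.

# Build the transformed analysis frame. `spec` is a named character vector
# mapping output term -> source column; names starting with "ln_" are
# log-transformed (source must be positive).
transform_frame <- function(data, response, spec, log_response = TRUE) {
  need <- unique(c(response, unname(spec)))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(.rows = nrow(data))
  resp_term <- if (log_response) paste0("ln_", response) else response
  resp_val <- data[[response]]
  if (log_response) {
    if (any(resp_val <= 0, na.rm = TRUE)) {
      abort(paste0("`", response, "` must be positive for log transformation"))
    }
    resp_val <- log(resp_val)
  }
  out[[resp_term]] <- resp_val
  for (term in names(spec)) {
    x <- data[[spec[[term]]]]
    if (startsWith(term, "ln_")) {
      if (any(x <= 0, na.rm = TRUE)) {
        abort(paste0("`", spec[[term]], "` must be positive for log transformation"))
      }
      x <- log(x)
    }
    out[[term]] <- x
  }
  attr(out, "response_term") <- resp_term
  out
}

climate_spec <- c(ln_ppfd = "ppfd", tg_c = "tg_c", ln_d = "d_kpa")

new_vcmax_fit <- function(fit, type, response_term, predictors, frame,
                          fallback = FALSE) {
  structure(list(fit = fit, type = type, response = response_term,
                 predictors = predictors, frame = frame, fallback = fallback),
            class = "vcmax_fit")
}

check_full_rank <- function(fit, predictors) {
  cf <- coef(fit)
  bad <- names(cf)[is.na(cf)]
  if (length(bad)) {
    abort(paste0("collinear or constant predictor column(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(fit)
}

#' Site-mean regression of ln Vcmax25 on climate
#'
#' Ordinary least squares of ln Vcmax25 on ln PPFD, growth temperature and
#' ln D, one data point per site. This is the fixed-effects counterpart of
#' [fit_all_species()]; its coefficients are directly comparable with the
#' theoretical elasticities of [climate_elasticities()].
#'
#' @param data Site-level data frame with columns `vcmax25`, `ppfd`, `tg_c`,
#'   `d_kpa` (site means joined with growing-season climate).
#' @return A `vcmax_fit` object; see [tidy.vcmax_fit()], [glance.vcmax_fit()]
#'   and [partial_residuals()].
#' @examples
#' d <- tibble::tibble(ppfd = c(200, 300, 400, 500, 600),
#'                     tg_c = c(5, 12, 18, 24, 28),
#'                     d_kpa = c(0.3, 0.5, 0.8, 1.2, 2.0),
#'                     vcmax25 = c(60, 55, 58, 50, 65))
#' tidy(fit_site_mean(d))
#' @export
fit_site_mean <- function(data) {
  frame <- transform_frame(data, "vcmax25", climate_spec)
  resp <- attr(frame, "response_term")
  preds <- names(climate_spec)
  if (nrow(frame) <= length(preds) + 1) {
    abort("need more sites than predictors + 1 for a site-mean fit")
  }
  f <- stats::reformulate(preds, response = resp)
  fit <- lm(f, data = frame)
  check_full_rank(fit, preds)
  new_vcmax_fit(fit, "ols", resp, preds, frame)
}

#' All-species mixed model of ln Vcmax25 on climate
#'
#' Linear mixed-effects model (REML) with ln PPFD, growth temperature and
#' ln D as fixed terms and crossed random intercepts for site and species
#' (crossed, not nested, because species can occur at several sites). If the
#' random-effects fit is singular, the function warns and falls back to OLS,
#' flagged in the returned object.
#'
#' @param data Record-level data frame with columns `site_id`, `species`,
#'   `vcmax25`, `ppfd`, `tg_c`, `d_kpa`.
#' @return A `vcmax_fit` object; [variance_components()] reports the shares
#'   of site, species and residual variance among the variation unexplained
#'   by climate.
#' @export
fit_all_species <- function(data) {
  if (dplyr::n_distinct(data$site_id) < 2 ||
        dplyr::n_distinct(data$species) < 2) {
    abort("need at least 2 sites and 2 species for the crossed mixed model")
  }
  frame <- transform_frame(data, "vcmax25", climate_spec)
  frame$site_id <- as.factor(data$site_id)
  frame$species <- as.factor(data$species)
  resp <- attr(frame, "response_term")
  preds <- names(climate_spec)
  f <- stats::as.formula(paste(
    resp, "~", paste(preds, collapse = " + "),
    "+ (1 | site_id) + (1 | species)"
  ))
  fit <- suppressMessages(lme4::lmer(f, data = frame, REML = TRUE,
                                     control = lme4::lmerControl(
                                       check.conv.singular = "ignore")))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warn("singular random-effects fit; falling back to ordinary least squares")
    ols <- lm(stats::reformulate(preds, response = resp), data = frame)
    check_full_rank(ols, preds)
    return(new_vcmax_fit(ols, "ols", resp, preds, frame, fallback = TRUE))
  }
  new_vcmax_fit(fit, "mixed", resp, preds, frame)
}

#' Theoretical Vcmax25 prediction for observation tables
#'
#' Evaluates the optimality prediction ([predict_vcmax()]) at each row's
#' growing-season climate and appends it as `vcmax25_pred`, leaving any
#' observed trait columns untouched.
#'
#' @param data Data frame with climate columns `ppfd`, `tg_c`, `d_kpa` and
#'   optionally `elevation_m`/`patm_pa`.
#' @inheritParams predict_vcmax
#' @return `data` as a tibble with `vcmax25_pred` appended.
#' @export
theoretical_prediction <- function(data, params = kinetic_params(),
                                   ca_ppm = 400) {
  env_cols <- intersect(c("ppfd", "tg_c", "d_kpa", "elevation_m", "patm_pa"),
                        names(data))
  pred <- predict_vcmax(data[env_cols], params = params, ca_ppm = ca_ppm)
  dplyr::mutate(as_tibble(data), vcmax25_pred = pred$vcmax25)
}

#' Model bias statistic
#'
#' Percentage deviation of a prediction from an observation,
#' `B = 100 * (pred - obs) / obs`. Scale-invariant: rescaling predictions
#' and observations by the same positive factor leaves B unchanged.
#'
#' @param pred Predicted values.
#' @param obs Observed values (> 0).
#' @return Bias in percent; exceeds -100 whenever predictions are positive.
#' @examples
#' bias(110, 100)
#' @export
bias <- function(pred, obs) {
  if (any(!is.finite(obs)) || any(obs <= 0)) abort("`obs` must be positive")
  100 * (pred - obs) / obs
}

#' Regress model bias on climate or leaf nutrients
#'
#' Tests whether the bias statistic ([bias()]) is related to the climate
#' drivers (which would point at something missing in the theory) or to leaf
#' nutrients (which would indicate nutrient effects beyond climate). Climate
#' covariates enter as ln PPFD, Tg and ln D; nutrient covariates as Narea
#' and ln Parea. With `random`, crossed random intercepts are added and the
#' model is fitted by [lme4::lmer()].
#'
#' @param data Data frame with a `bias` column and the covariate source
#'   columns (`ppfd`, `tg_c`, `d_kpa` or `narea`, `parea`; plus grouping
#'   columns when `random` is used).
#' @param covariates `"climate"` or `"nutrients"`.
#' @param random Optional character vector of grouping columns (e.g.
#'   `c("site_id", "species")`) for random intercepts.
#' @return A `vcmax_fit` object with response `bias`.
#' @export
bias_regression <- function(data, covariates = c("climate", "nutrients"),
                            random = NULL) {
  covariates <- match.arg(covariates)
  spec <- if (covariates == "climate") climate_spec else
    c(narea = "narea", ln_parea = "parea")
  keep <- stats::complete.cases(data[unique(c("bias", unname(spec), random))])
  if (sum(!keep) > 0) {
    warn(sprintf("%d row(s) with missing covariates excluded", sum(!keep)))
  }
  data <- data[keep, , drop = FALSE]
  frame <- transform_frame(data, "bias", spec, log_response = FALSE)
  preds <- names(spec)
  if (is.null(random)) {
    fit <- lm(stats::reformulate(preds, response = "bias"), data = frame)
    check_full_rank(fit, preds)
    return(new_vcmax_fit(fit, "ols", "bias", preds, frame))
  }
  for (g in random) frame[[g]] <- as.factor(data[[g]])
  f <- stats::as.formula(paste(
    "bias ~", paste(preds, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")
  ))
  fit <- suppressMessages(lme4::lmer(f, data = frame, REML = TRUE,
                                     control = lme4::lmerControl(
                                       check.conv.singular = "ignore")))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warn("singular random-effects fit; falling back to ordinary least squares")
    ols <- lm(stats::reformulate(preds, response = "bias"), data = frame)
    return(new_vcmax_fit(ols, "ols", "bias", preds, frame, fallback = TRUE))
  }
  new_vcmax_fit(fit, "mixed", "bias", preds, frame)
}

#' Partial residuals for one predictor
#'
#' Returns the response adjusted to hold all other predictors at their
#' median values: residual + intercept + fitted component of the chosen
#' predictor + the other coefficients evaluated at their medians. For an
#' ordinary least squares fit, regressing the partial residuals on the
#' predictor reproduces the fitted coefficient exactly, and a
#' single-predictor model returns the observations unchanged.
#'
#' @param object A `vcmax_fit`.
#' @param predictor Name of a fitted predictor term (e.g. `"ln_d"`).
#' @return Tibble with the predictor values (`x`, on the transformed scale
#'   used in the fit) and `partial_residual`.
#' @export
partial_residuals <- function(object, predictor) {
  stopifnot(inherits(object, "vcmax_fit"))
  if (!predictor %in% object$predictors) {
    abort(paste0("unknown predictor `", predictor, "`; fitted terms are: ",
                 paste(object$predictors, collapse = ", ")))
  }
  b <- if (object$type == "mixed") lme4::fixef(object$fit) else coef(object$fit)
  frame <- object$frame
  x <- frame[[predictor]]
  others <- setdiff(object$predictors, predictor)
  anchor <- b[["(Intercept)"]] +
    sum(vapply(others, function(k) b[[k]] * median(frame[[k]]), numeric(1)))
  tibble(x = x,
         partial_residual = unname(residuals(object$fit)) +
           b[[predictor]] * x + anchor)
}

#' Leaf-nutrient versus soil regressions
#'
#' Site-mean OLS of Narea (untransformed) and ln Parea on the in-situ soil
#' properties (C:N ratio, ln total P, pH) jointly, mirroring the leaf/soil
#' analysis of nutrient supply effects.
#'
#' @param site_means Site-mean table (see [aggregate_site_means()]) with
#'   soil columns `ph`, `c_to_n`, `total_p`.
#' @return Named list of `vcmax_fit` objects (`narea`, `parea`), or an empty
#'   list with a warning when soil columns are absent.
#' @export
leaf_soil_regressions <- function(site_means) {
  soil_cols <- c("ph", "c_to_n", "total_p")
  if (!all(soil_cols %in% names(site_means))) {
    warn("no soil columns present; skipping leaf-soil regressions")
    return(list())
  }
  spec <- c(c_to_n = "c_to_n", ln_total_p = "total_p", ph = "ph")
  fits <- list()
  for (trait in c("narea", "parea")) {
    if (!trait %in% names(site_means)) next
    keep <- stats::complete.cases(site_means[c(trait, soil_cols)])
    d <- site_means[keep, , drop = FALSE]
    frame <- transform_frame(d, trait, spec, log_response = trait == "parea")
    resp <- attr(frame, "response_term")
    fit <- lm(stats::reformulate(names(spec), response = resp), data = frame)
    check_full_rank(fit, names(spec))
    if (any(vapply(names(spec), function(k) sd(frame[[k]]) == 0, logical(1)))) {
      abort("constant soil column(s): no variance to regress on")
    }
    fits[[trait]] <- new_vcmax_fit(fit, "ols", resp, names(spec), frame)
  }
  fits
}

#' Variance components of a mixed `vcmax_fit`
#'
#' Shares of the variation left unexplained by the fixed (climate) terms
#' attributable to site identity, species identity and the residual.
#'
#' @param object A `vcmax_fit` of type `"mixed"`.
#' @return Tibble with `component`, `variance`, `fraction` (fractions sum
#'   to 1 across site, species and residual).
#' @export
variance_components <- function(object) {
  stopifnot(inherits(object, "vcmax_fit"))
  if (object$type != "mixed") {
    abort("variance components are only defined for mixed-model fits")
  }
  vc <- as.data.frame(lme4::VarCorr(object$fit))
  v <- setNames(vc$vcov, vc$grp)
  total <- sum(v)
  tibble(component = names(v), variance = unname(v),
         fraction = unname(v) / total)
}

#' Influence diagnostics and refitting without extreme points
#'
#' Cook's distances for an OLS `vcmax_fit`, and a utility that refits the
#' model with the `k` most influential points removed. Points are never
#' dropped automatically; the refit is for sensitivity checking only.
#'
#' @param object A `vcmax_fit` of type `"ols"`.
#' @param k Number of highest-Cook's-distance points to drop.
#' @return `influence_diagnostics()`: tibble with row index and `cooks_d`.
#'   `refit_without_influential()`: a new `vcmax_fit`.
#' @export
influence_diagnostics <- function(object) {
  stopifnot(inherits(object, "vcmax_fit"))
  if (object$type != "ols") abort("influence diagnostics require an OLS fit")
  d <- cooks.distance(object$fit)
  tibble(row = seq_along(d), cooks_d = as.numeric(d))
}

#' @rdname influence_diagnostics
#' @export
refit_without_influential <- function(object, k = 3) {
  diag <- influence_diagnostics(object)
  drop_rows <- diag$row[order(-diag$cooks_d)][seq_len(min(k, nrow(diag)))]
  frame <- object$frame[-drop_rows, , drop = FALSE]
  f <- stats::reformulate(object$predictors, response = object$response)
  fit <- lm(f, data = frame)
  new_vcmax_fit(fit, "ols", object$response, object$predictors, frame)
}

#' @export
print.vcmax_fit <- function(x, ...) {
  cat(sprintf("<vcmax_fit: %s%s> response %s, n = %d\n",
              x$type, if (x$fallback) " (OLS fallback)" else "",
              x$response, nrow(x$frame)))
  print(tidy(x))
  invisible(x)
}

#' Tidy coefficients of a `vcmax_fit`
#'
#' One row per model term with estimate and standard error. For mixed
#' models, test statistics and p-values use the large-sample normal
#' approximation for the fixed effects.
#'
#' @param x A `vcmax_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.vcmax_fit <- function(x, ...) {
  if (x$type == "mixed") {
    b <- lme4::fixef(x$fit)
    se <- sqrt(diag(as.matrix(vcov(x$fit))))
    z <- b / se
    return(tibble(term = names(b), estimate = unname(b),
                  std.error = unname(se), statistic = unname(z),
                  p.value = 2 * pnorm(-abs(unname(z)))))
  }
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std.error = unname(s[, 2]), statistic = unname(s[, 3]),
         p.value = unname(s[, 4]))
}

#' Model-level summary of a `vcmax_fit`
#'
#' For OLS fits: R-squared, adjusted R-squared, residual sigma and n. For
#' mixed fits: marginal R-squared (fixed effects only) and conditional
#' R-squared (fixed plus random), the site/species/residual variance
#' fractions, and n. The marginal value is the one comparable with an OLS
#' R-squared on the same records.
#'
#' @inheritParams tidy.vcmax_fit
#' @return One-row tibble.
#' @export
glance.vcmax_fit <- function(x, ...) {
  if (x$type == "mixed") {
    vc <- variance_components(x)
    fixed_pred <- as.numeric(model.matrix(x$fit) %*% lme4::fixef(x$fit))
    var_f <- var(fixed_pred)
    var_r <- sum(vc$variance[vc$component != "Residual"])
    var_e <- vc$variance[vc$component == "Residual"]
    frac <- setNames(vc$fraction, vc$component)
    return(tibble(
      r.squared.marginal = var_f / (var_f + var_r + var_e),
      r.squared.conditional = (var_f + var_r) / (var_f + var_r + var_e),
      frac_site = unname(frac[["site_id"]]),
      frac_species = unname(frac[["species"]]),
      frac_residual = unname(frac[["Residual"]]),
      nobs = nrow(x$frame)
    ))
  }
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, nobs = nrow(x$frame))
}
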