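# Nutrient co-limitation of Vcmax25: smooth-minimum (log-sum-exp) regression
# on leaf N and P limbs, k-sensitivity, and limitation classification.

#' Smooth minimum (log-sum-exp)
#'
#' Differentiable approximation to `min(x, y)`:
#' `Z = -(1/k) * ln(exp(-k*x) + exp(-k*y))`, evaluated in an overflow-safe
#' max-shifted form. The approximation error is bounded by
#' `min(x, y) - ln(2)/k <= Z <= min(x, y)`, with the bound attained at
#' `x = y`; larger `k` gives a sharper minimum.
#'
#' @param x,y Numeric vectors (recycled).
#' @param k Sharpness, > 0.
#' @return The smooth minimum.
#' @examples
#' smooth_min(1, 1, 10) # 1 - log(2)/10
#' smooth_min(0, 5, 20) # ~ 0
#' @export
smooth_min <- function(x, y, k) {
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite")
  }
  if (any(!is.finite(k)) || any(k <= 0)) abort("`k` must be positive")
  m <- pmin(x, y)
  m - log(exp(-k * (x - m)) + exp(-k * (y - m))) / k
}

limb_values <- function(coef, tn, tp) {
  list(n = coef[["a_n"]] + coef[["b_n"]] * tn,
       p = coef[["a_p"]] + coef[["b_p"]] * tp)
}

# deterministic low-discrepancy jitter in [-1, 1] (golden-ratio sequence);
# keeps multi-start reproducible without touching the RNG stream
det_jitter <- function(i, dim = 4) {
  g <- (sqrt(5) - 1) / 2
  2 * (((i * 100 + seq_len(dim) * 17) * g) %% 1) - 1
}

minfunc_frame <- function(data, response, log_response, limb_transform) {
  need <- c(response, "narea", "parea")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[need])
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    warn(sprintf("%d record(s) with missing response or nutrients skipped",
                 n_drop))
  }
  d <- data[keep, , drop = FALSE]
  if (any(d$narea <= 0) || any(d$parea <= 0)) {
    abort("`narea` and `parea` must be positive")
  }
  z <- d[[response]]
  if (log_response) {
    if (any(z <= 0)) abort("response must be positive for log transformation")
    z <- log(z)
  }
  tf <- if (limb_transform == "log") log else identity
  tibble(z = z, tn = tf(d$narea), tp = tf(d$parea),
         narea = d$narea, parea = d$parea)
}

#' Fit the smooth-minimum nutrient co-limitation model
#'
#' Nonlinear least squares of (by default, log) Vcmax25 on the smooth
#' minimum of two nutrient limbs,
#' `z = smooth_min(a_N + b_N * f(Narea), a_P + b_P * f(Parea), k)`, with
#' `f = ln` by default and the sharpness `k` held fixed (large `k`
#' approaches a hard minimum; `k` is deliberately not estimated jointly
#' because it is poorly identified). Optimization is quasi-Newton with an
#' analytic gradient from a multi-start: limb-wise linear fits shifted
#' towards the upper envelope of the data, plus deterministic jittered
#' restarts. The run with the lowest residual sum of squares wins.
#'
#' @param data Data frame with `narea`, `parea` (g/m2, positive) and the
#'   response column.
#' @param k Sharpness of the smooth minimum (default 20).
#' @param response Response column name (default `"vcmax25"`).
#' @param log_response Model the natural log of the response (default)?
#' @param limb_transform `"log"` (limbs linear in ln nutrient, default) or
#'   `"identity"`.
#' @param n_starts Number of optimization starts (>= 1).
#' @return A `minfunc_fit` object: limb coefficients with approximate
#'   standard errors (from the Gauss-Newton Hessian), RSS, R-squared, AIC,
#'   per-limb active fractions, and the model frame.
#' @seealso [classify_limitation()], [k_sensitivity()],
#'   [minfunc_model_comparison()]
#' @export
fit_minfunc <- function(data, k = 20, response = "vcmax25",
                        log_response = TRUE,
                        limb_transform = c("log", "identity"),
                        n_starts = 10) {
  limb_transform <- match.arg(limb_transform)
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be >= 1")
  frame <- minfunc_frame(data, response, log_response, limb_transform)
  if (nrow(frame) < 10) abort("need at least 10 complete records")
  z <- frame$z; tn <- frame$tn; tp <- frame$tp

  rss_fn <- function(th) {
    lv <- limb_values(setNames(th, c("a_n", "b_n", "a_p", "b_p")), tn, tp)
    sum((z - smooth_min(lv$n, lv$p, k))^2)
  }
  grad_fn <- function(th) {
    lv <- limb_values(setNames(th, c("a_n", "b_n", "a_p", "b_p")), tn, tp)
    m <- pmin(lv$n, lv$p)
    en <- exp(-k * (lv$n - m)); ep <- exp(-k * (lv$p - m))
    wn <- en / (en + ep); wp <- 1 - wn
    r <- z - (m - log(en + ep) / k)
    -2 * c(sum(r * wn), sum(r * wn * tn), sum(r * wp), sum(r * wp * tp))
  }

  # limb-wise initial values shifted towards the upper envelope: the hard
  # minimum pulls observations below whichever limb is not limiting, so a
  # marginal least-squares line underestimates the limb intercept
  start_limb <- function(t) {
    f <- lm(z ~ t)
    c(coef(f)[1] + quantile(residuals(f), 0.9, names = FALSE), coef(f)[2])
  }
  base <- c(start_limb(tn), start_limb(tp))
  scale <- pmax(abs(base), 0.5)
  starts <- lapply(seq_len(max(1, n_starts)), function(i) {
    if (i == 1) base else base + 0.4 * scale * det_jitter(i - 1)
  })

  runs <- lapply(starts, function(s) {
    tryCatch(
      optim(s, rss_fn, grad_fn, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (!length(runs)) abort("min-function optimization failed from all starts")
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  if (best$convergence != 0) {
    warn("min-function fit did not fully converge; returning best solution found")
  }
  th <- setNames(best$par, c("a_n", "b_n", "a_p", "b_p"))

  lv <- limb_values(th, tn, tp)
  fitted <- smooth_min(lv$n, lv$p, k)
  rss <- sum((z - fitted)^2)
  tss <- sum((z - mean(z))^2)
  n <- length(z)
  sigma2 <- rss / max(n - 4, 1)
  # Gauss-Newton covariance from the Jacobian of the smooth minimum
  m <- pmin(lv$n, lv$p)
  wn <- exp(-k * (lv$n - m)) / (exp(-k * (lv$n - m)) + exp(-k * (lv$p - m)))
  J <- cbind(a_n = wn, b_n = wn * tn, a_p = 1 - wn, b_p = (1 - wn) * tp)
  se <- tryCatch(sqrt(diag(sigma2 * solve(crossprod(J)))),
                 error = function(e) rep(NA_real_, 4))
  active <- c(n = mean(wn > 0.5), p = mean(wn <= 0.5))
  if (any(active * n < 2)) {
    warn(sprintf(
      "limb `%s` is limiting for fewer than 2 records: its parameters are unidentifiable",
      names(active)[active * n < 2][1]))
  }
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  structure(list(
    k = k, coef = th, se = setNames(se, names(th)),
    limb_transform = limb_transform, log_response = log_response,
    response = response, fitted = fitted, rss = rss, r2 = 1 - rss / tss,
    aic = -2 * ll + 2 * 5, logLik = ll, n = n, frame = frame,
    active_frac = active, convergence = best$convergence
  ), class = "minfunc_fit")
}

#' @export
print.minfunc_fit <- function(x, ...) {
  cat(sprintf("<minfunc_fit> k = %g, n = %d, RSS = %.4g, R2 = %.3f\n",
              x$k, x$n, x$rss, x$r2))
  cat(sprintf("  N limb: %.4g %+.4g * %s(Narea)\n", x$coef[["a_n"]],
              x$coef[["b_n"]], if (x$limb_transform == "log") "ln" else ""))
  cat(sprintf("  P limb: %.4g %+.4g * %s(Parea)\n", x$coef[["a_p"]],
              x$coef[["b_p"]], if (x$limb_transform == "log") "ln" else ""))
  invisible(x)
}

#' Predict from a fitted smooth-minimum model
#'
#' @param object A `minfunc_fit`.
#' @param newdata Optional data frame with `narea`, `parea`; defaults to the
#'   fitting data.
#' @param type `"response"` (natural scale) or `"link"` (the fitted scale,
#'   i.e. log response when the model was fitted on logs).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.minfunc_fit <- function(object, newdata = NULL,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    z <- object$fitted
  } else {
    tf <- if (object$limb_transform == "log") log else identity
    lv <- limb_values(object$coef, tf(newdata$narea), tf(newdata$parea))
    z <- smooth_min(lv$n, lv$p, object$k)
  }
  if (type == "response" && object$log_response) exp(z) else z
}

#' Sensitivity of the co-limitation fit to the sharpness k
#'
#' Refits the smooth-minimum model over a grid of `k` values. When the data
#' are generated by a hard minimum, the residual sum of squares decreases
#' and then plateaus as `k` grows; when the true transition is smooth, small
#' `k` fits best.
#'
#' @inheritParams fit_minfunc
#' @param k_grid Numeric vector of at least 3 sharpness values (a shorter
#'   grid is allowed but gives a table with fewer rows).
#' @return Tibble with `k`, `rss`, `r_squared`.
#' @export
k_sensitivity <- function(data, k_grid = c(1, 2, 5, 10, 20, 50),
                          response = "vcmax25", log_response = TRUE,
                          limb_transform = c("log", "identity"),
                          n_starts = 10) {
  limb_transform <- match.arg(limb_transform)
  fits <- lapply(k_grid, function(kk) {
    fit_minfunc(data, k = kk, response = response,
                log_response = log_response, limb_transform = limb_transform,
                n_starts = n_starts)
  })
  tibble(k = k_grid,
         rss = vapply(fits, `[[`, numeric(1), "rss"),
         r_squared = vapply(fits, `[[`, numeric(1), "r2"))
}

#' Classify records by their limiting nutrient
#'
#' Labels each record by the limb with the lower prediction (the limiting
#' nutrient), reports the fraction limited by each, and returns the boundary
#' curve in the (Parea, Narea) plane along which the two limb predictions
#' are equal.
#'
#' @param object A `minfunc_fit`.
#' @param data Optional data frame with `narea`, `parea`; defaults to the
#'   fitting data. Records with missing nutrients are skipped with a count.
#' @return List with `labels` (tibble: `narea`, `parea`, `limitation`,
#'   `margin`), `fractions` (named numeric, shares of N- and P-limited
#'   records) and `boundary` (tibble: `parea`, `narea` sampled along the
#'   equal-limb curve).
#' @export
classify_limitation <- function(object, data = NULL) {
  stopifnot(inherits(object, "minfunc_fit"))
  if (is.null(data)) {
    d <- object$frame
  } else {
    keep <- stats::complete.cases(data[c("narea", "parea")])
    if (sum(!keep)) {
      warn(sprintf("%d record(s) with missing nutrients skipped", sum(!keep)))
    }
    d <- data[keep, , drop = FALSE]
  }
  tf <- if (object$limb_transform == "log") log else identity
  lv <- limb_values(object$coef, tf(d$narea), tf(d$parea))
  labels <- tibble(
    narea = d$narea, parea = d$parea,
    limitation = ifelse(lv$n < lv$p, "N-limited", "P-limited"),
    margin = abs(lv$n - lv$p)
  )
  fr <- c("N-limited" = mean(labels$limitation == "N-limited"),
          "P-limited" = mean(labels$limitation == "P-limited"))
  # equal-limb curve: a_n + b_n f(N) = a_p + b_p f(P), solved for N
  cf <- object$coef
  p_seq <- exp(seq(log(min(d$parea)), log(max(d$parea)), length.out = 100))
  fn <- (cf[["a_p"]] - cf[["a_n"]] + cf[["b_p"]] * tf(p_seq)) / cf[["b_n"]]
  n_seq <- if (object$limb_transform == "log") exp(fn) else fn
  list(labels = labels, fractions = fr,
       boundary = tibble(parea = p_seq, narea = n_seq))
}

#' Compare the co-limitation model against linear alternatives
#'
#' Fits the smooth-minimum model and ordinary linear regressions of the
#' (log) response on ln Narea, ln Parea, both, and both with interaction,
#' and tabulates their goodness of fit for model selection.
#'
#' @inheritParams fit_minfunc
#' @return Tibble with `model`, `n_par`, `rss`, `r_squared`, `aic`.
#' @export
minfunc_model_comparison <- function(data, k = 20, response = "vcmax25",
                                     log_response = TRUE,
                                     limb_transform = c("log", "identity"),
                                     n_starts = 10) {
  limb_transform <- match.arg(limb_transform)
  mf <- fit_minfunc(data, k = k, response = response,
                    log_response = log_response,
                    limb_transform = limb_transform, n_starts = n_starts)
  frame <- mf$frame
  lms <- list(
    "linear N" = lm(z ~ tn, data = frame),
    "linear P" = lm(z ~ tp, data = frame),
    "linear N + P" = lm(z ~ tn + tp, data = frame),
    "linear N x P" = lm(z ~ tn * tp, data = frame)
  )
  row <- function(name, rss, r2, aic, npar) {
    tibble(model = name, n_par = npar, rss = rss, r_squared = r2, aic = aic)
  }
  out <- dplyr::bind_rows(
    row("smooth minimum", mf$rss, mf$r2, mf$aic, 4L),
    dplyr::bind_rows(lapply(names(lms), function(nm) {
      f <- lms[[nm]]
      rss <- sum(residuals(f)^2)
      row(nm, rss, summary(f)$r.squared, AIC(f), length(coef(f)))
    }))
  )
  dplyr::arrange(out, .data$aic)
}

#' @export
tidy.minfunc_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std.error = unname(x$se))
}

#' @export
glance.minfunc_fit <- function(x, ...) {
  tibble(k = x$k, rss = x$rss, r.squared = x$r2, AIC = x$aic, nobs = x$n)
}
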