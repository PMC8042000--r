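# ggplot2 display methods for fitted objects.

#' Partial-residual panels for a climate fit
#'
#' One panel per fitted predictor showing the partial residuals
#' ([partial_residuals()]) with the fitted line; the slope of each line is
#' the corresponding model coefficient.
#'
#' @param object A `vcmax_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vcmax_fit <- function(object, ...) {
  b <- if (object$type == "mixed") lme4::fixef(object$fit) else
    coef(object$fit)
  panels <- dplyr::bind_rows(lapply(object$predictors, function(p) {
    pr <- partial_residuals(object, p)
    dplyr::mutate(pr, predictor = p,
                  fit_line = b[[p]] * (pr$x - mean(pr$x)) +
                    mean(pr$partial_residual))
  }))
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$x,
                                       y = .data$partial_residual)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit_line), colour = "#2166ac") +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "predictor (transformed scale)",
                  y = paste("partial residual of", object$response)) +
    ggplot2::theme_minimal()
}

#' Nutrient co-limitation plane
#'
#' Leaf records in the (Parea, Narea) plane coloured by their limiting
#' nutrient under a fitted smooth-minimum model, with the equal-limb
#' boundary curve.
#'
#' @param object A `minfunc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.minfunc_fit <- function(object, ...) {
  cl <- classify_limitation(object)
  ggplot2::ggplot(cl$labels, ggplot2::aes(x = .data$parea, y = .data$narea,
                                          colour = .data$limitation)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = cl$boundary, ggplot2::aes(colour = NULL),
                       colour = "black", linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c("N-limited" = "#b2182b",
                                            "P-limited" = "#2166ac")) +
    ggplot2::labs(x = expression(P[area] ~ (g ~ m^-2)),
                  y = expression(N[area] ~ (g ~ m^-2))) +
    ggplot2::theme_minimal()
}

#' Sharpness sensitivity curve
#'
#' Residual sum of squares of the co-limitation fit against the smooth-
#' minimum sharpness k (log axis). A plateau at large k indicates the data
#' behave like a hard minimum.
#'
#' @param sens Output of [k_sensitivity()].
#' @return A ggplot object.
#' @export
plot_k_sensitivity <- function(sens) {
  ggplot2::ggplot(sens, ggplot2::aes(x = .data$k, y = .data$rss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sharpness k", y = "residual sum of squares") +
    ggplot2::theme_minimal()
}
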