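# ggplot2 displays for the main result types.

#' @rdname cv_importance
#' @param object A `cv_importance` object.
#' @export
autoplot.cv_importance <- function(object, ...) {
  td <- tidy(object)
  td$predictor <- stats::reorder(td$predictor, td$importance)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$importance,
                                   y = .data$predictor)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$importance - .data$sd,
      xmax = .data$importance + .data$sd), linewidth = 0.3, size = 0.25) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::labs(x = "cross-validated permutation importance",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname group_means_ci
#' @param object A `cm_group_means` object.
#' @param ... Unused.
#' @export
autoplot.cm_group_means <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$group),
                                       y = .data$mean,
                                       colour = .data$stratum)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "number of experienced subtypes",
                  y = "physical multimorbidity (mean, 95% CI)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname predicted_surface
#' @param object A `cm_surface` object.
#' @param ... Unused.
#' @export
autoplot.cm_surface <- function(object, ...) {
  exposure <- attr(object, "exposure") %||% "duration"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[exposure]],
                                       y = .data$predicted,
                                       colour = .data$age_group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::labs(x = sprintf("%s of maltreatment (years)", exposure),
                  y = "estimated physical multimorbidity",
                  colour = "age group") +
    ggplot2::theme_minimal()
}
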