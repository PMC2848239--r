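#' Heatmap of a simplex scan
#'
#' Plots mean sensitivity (or another scanned measure) over the
#' `(b0, b1)` projection of the weight simplex, the standard way to read
#' where on the generative-discriminative continuum a classifier
#' performs best. The corners and mid-edges correspond to the classical
#' learning principles.
#'
#' @param object A `"blend_scan"` tibble from [simplex_scan()].
#' @param measure Column to plot (default `"mean_sensitivity"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot blend_scan
#' @export
autoplot.blend_scan <- function(object, measure = "mean_sensitivity", ...) {
  step <- attr(object, "step") %||% 0.05
  ggplot2::ggplot(object, ggplot2::aes(.data$b0, .data$b1,
                                       fill = .data[[measure]])) +
    ggplot2::geom_tile(width = step, height = step) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(beta[0] ~ "(conditional likelihood weight)"),
      y = expression(beta[1] ~ "(likelihood weight)"),
      fill = measure,
      title = "Performance over the learning-principle simplex"
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of per-repeat sensitivities
#'
#' @param object A `"blend_holdout"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot blend_holdout
#' @export
autoplot.blend_holdout <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(.data$sensitivity)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey30") +
    ggplot2::labs(
      x = sprintf("sensitivity at specificity %.4g", object$config$specificity),
      y = "hold-out repeats"
    ) +
    ggplot2::theme_minimal()
}

#' Per-position probability profile of a fitted classifier
#'
#' @param object A `"blend_fit"` object.
#' @param ... Unused.
#' @return A ggplot object faceted by class.
#' @method autoplot blend_fit
#' @export
autoplot.blend_fit <- function(object, ...) {
  td <- tidy.blend_fit(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$position, .data$estimate,
                                   fill = .data$symbol)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~class, ncol = 1) +
    ggplot2::labs(x = "motif position", y = "probability",
                  title = "Fitted PWM columns") +
    ggplot2::theme_minimal()
}
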