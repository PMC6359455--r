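#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Diagnostic plot for a descriptor fit
#'
#' Observed vs fitted infinite-dilution ln gamma per probe, with the
#' diagonal.
#'
#' @param object A `psp_fit` from [fit_descriptors()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psp_fit <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed,
                                   label = .data$probe)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = expression(ln ~ gamma[calc]^infinity),
      y = expression(ln ~ gamma[obs]^infinity),
      title = "Descriptor fit: per-probe agreement",
      subtitle = sprintf("rms residual %.3g", object$rms_residual)) +
    ggplot2::theme_minimal()
}

#' Predicted vs experimental solubility scatter
#'
#' Simple diagnostic scatter of experimental against predicted log10
#' solubilities with the ordinary-least-squares line and the diagonal.
#'
#' @param data Data frame with the two columns.
#' @param predicted,experimental Column names (tidy-eval).
#' @return A ggplot object.
#' @export
plot_prediction_scatter <- function(data, predicted, experimental) {
  pred <- rlang::enquo(predicted)
  obs <- rlang::enquo(experimental)
  ggplot2::ggplot(data, ggplot2::aes(x = !!pred, y = !!obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "predicted log10 solubility",
                  y = "experimental log10 solubility") +
    ggplot2::theme_minimal()
}

#' Surface-energy component bar chart
#'
#' Stacked view of the non-hydrogen-bonding and hydrogen-bonding
#' contributions to the total surface energy per compound.
#'
#' @param components Output of [surface_components()] (needs `name`,
#'   `gamma_VES`, `gamma_hb`).
#' @return A ggplot object.
#' @export
plot_surface_components <- function(components) {
  long <- tidyr::pivot_longer(
    components[, c("name", "gamma_VES", "gamma_hb")],
    cols = c("gamma_VES", "gamma_hb"),
    names_to = "component", values_to = "energy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name, y = .data$energy,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(gamma ~ (mJ/m^2)),
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
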