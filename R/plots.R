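#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a prognosis curve
#'
#' Point estimate with a pointwise confidence ribbon over base time `t`.
#'
#' @param object A `prognosis_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prognosis_curve
#' @export
autoplot.prognosis_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$defined & is.finite(df$estimate), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "years since diagnosis (t)",
      y = attr(object, "label"),
      title = paste0(attr(object, "label"), " (Δ = ",
                     attr(object, "delta"), " y)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a solved plug-in path
#'
#' Step curves of every state component, with pointwise 95% bands when the
#' covariance path is available.
#'
#' @param object A `plugin_path`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plugin_path
#' @export
autoplot.plugin_path <- function(object, ...) {
  df <- tidy.plugin_path(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate,
                                         colour = .data$state)) +
    ggplot2::geom_step()
  if (!is.null(object$v)) {
    df$se <- sqrt(pmax(df$variance, 0))
    gg <- gg + ggplot2::geom_step(ggplot2::aes(y = .data$estimate - 1.96 * .data$se),
                                  linetype = "dashed", alpha = 0.6) +
      ggplot2::geom_step(ggplot2::aes(y = .data$estimate + 1.96 * .data$se),
                         linetype = "dashed", alpha = 0.6)
  }
  gg + ggplot2::labs(x = "years since diagnosis", y = "estimate") +
    ggplot2::theme_minimal()
}
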