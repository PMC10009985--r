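# ggplot2 figures for the post-estimation tables

#' Plot willingness-to-accept estimates
#'
#' Horizontal bar chart of WTA (ETB/month) per attribute coefficient, with
#' interval whiskers when present.
#'
#' @param object A `dce_wta` tibble from [wta()] or [wta_interval()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dce_wta <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$coefficient,
                                                       .data$estimate))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Willingness to accept (ETB/month)", y = NULL)
  if (all(c("conf.low", "conf.high") %in% names(object)))
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2)
  p
}

#' @rdname autoplot.dce_wta
#' @export
plot_wta <- function(object, ...) autoplot.dce_wta(object, ...)

#' Plot relative importance of attributes
#'
#' Grouped bar chart of normalised importance scores per class (and
#' pooled).
#'
#' @param object A `dce_importance` tibble from [relative_importance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dce_importance <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$score, y = .data$attribute,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Relative importance (most important = 1)", y = NULL,
                  fill = NULL)
}

#' @rdname autoplot.dce_importance
#' @export
plot_relative_importance <- function(object, ...)
  autoplot.dce_importance(object, ...)

#' Plot uptake-rate changes
#'
#' Bar chart of the marginal uptake change (percentage points) per policy
#' move, with interval whiskers when present.
#'
#' @param object A `dce_uptake` tibble from [uptake_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dce_uptake <- function(object, ...) {
  lab <- paste(object$attribute, object$policy_level, sep = ": ")
  d <- dplyr::mutate(object, move = lab)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                       y = stats::reorder(.data$move,
                                                          .data$estimate))) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Uptake-rate change (percentage points)", y = NULL)
  if (all(c("conf.low", "conf.high") %in% names(d)))
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2)
  p
}

#' @rdname autoplot.dce_uptake
#' @export
plot_uptake <- function(object, ...) autoplot.dce_uptake(object, ...)
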