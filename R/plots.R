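#' Plot a tuning function with confidence bounds
#'
#' @param object A `navgam_tuning` tibble from [extract_tuning()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.navgam_tuning <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid,
                                       y = .data$response)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.8, colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = attr(object, "preferred"),
                        linetype = 3) +
    ggplot2::labs(x = attr(object, "variable"), y = "rate (Hz)",
                  title = paste0(attr(object, "unit_id"), " (p = ",
                                 signif(attr(object, "p_value"), 2), ")")) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-area tuned fractions with confidence intervals
#'
#' @param fractions Tibble from [fraction_tuned()].
#' @return A ggplot.
#' @export
plot_tuned_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$term, y = .data$fraction,
                               fill = .data$area)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "fraction tuned") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatter of a 2-D embedding colored by label
#'
#' @param object A `cluster_assignment` with an `embedding` element.
#' @param colour Optional vector (e.g. area labels); defaults to cluster
#'   labels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_assignment <- function(object, colour = NULL, ...) {
  if (is.null(object$embedding)) stop("no embedding in this assignment")
  df <- tibble::tibble(x = object$embedding[, 1], y = object$embedding[, 2],
                       colour = if (is.null(colour)) {
                         factor(object$labels)
                       } else factor(colour))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$colour)) +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::labs(x = "embedding 1", y = "embedding 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the sender-receiver coupling-fraction grid
#'
#' @param fractions Tibble from [coupling_fractions()].
#' @return A ggplot.
#' @export
plot_coupling_grid <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$receiver_area,
                               y = .data$sender_area,
                               fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$fraction), "",
                     sprintf("%.2f", .data$fraction))), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey90") +
    ggplot2::labs(x = "receiver", y = "sender", fill = "coupled") +
    ggplot2::theme_minimal()
}
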