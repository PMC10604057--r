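#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Scatter of pairwise means against differences with the mean difference
#' (solid) and the 1.96-SD limits of agreement (dashed).
#'
#' @param object A [bland_altman()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean_xy, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = s$mean_diff, colour = "red") +
    ggplot2::geom_hline(yintercept = c(s$loa_lower, s$loa_upper),
                        colour = "blue", linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference", title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Success-rate curve plot
#'
#' @param object A [success_curve()] tibble (optionally with a `parameter`
#'   column for one panel line per parameter).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot success_curve
#' @export
autoplot.success_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$rate))
  if ("parameter" %in% names(object)) {
    p <- p + ggplot2::aes(colour = .data$parameter)
  }
  p +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Error threshold (deg)", y = "Success rate") +
    ggplot2::theme_minimal()
}

#' Plot a phantom radiograph with its landmarks
#'
#' @param annotated An `annotated_image` from [render_radiograph()].
#' @param show_landmarks Overlay the annotation points.
#' @return A ggplot object.
#' @export
plot_radiograph <- function(annotated, show_landmarks = TRUE) {
  stopifnot(inherits(annotated, "annotated_image"))
  img <- annotated$image
  df <- tidyr::expand_grid(y = seq_len(nrow(img)) - 1L,
                           x = seq_len(ncol(img)) - 1L)
  df$value <- as.numeric(t(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (show_landmarks) {
    p <- p + ggplot2::geom_point(
      data = annotated$landmarks,
      ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, colour = "red", size = 0.8
    )
  }
  p
}

#' Training loss curves of a cascade model
#'
#' @param model A `cascade_model`.
#' @return A ggplot object, one line per regressor head.
#' @export
plot_training_history <- function(model) {
  stopifnot(inherits(model, "cascade_model"))
  ggplot2::ggplot(model$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$head)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "MAE loss (normalized coords)") +
    ggplot2::theme_minimal()
}
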