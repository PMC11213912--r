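#' Tidy a calibration result
#'
#' @param x a `tq_calibration` from [calibrate()].
#' @param ... unused.
#' @return One row per slide: scores, z-disagreement, inlier flag and the
#'   calibrated score (`k * computational`, for every slide).
#' @export
tidy.tq_calibration <- function(x, ...) {
  tibble::tibble(
    slide_id = x$slide_id,
    computational = x$computational,
    visual = x$visual,
    z_disagreement = x$z_disagreement,
    inlier = x$inlier,
    calibrated = x$calibrated
  )
}

#' Glance at a calibration result
#'
#' @param x a `tq_calibration`.
#' @param ... unused.
#' @return One-row tibble with the scale `k`, slide and outlier counts.
#' @export
glance.tq_calibration <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_slides = length(x$inlier), n_outliers = sum(!x$inlier),
    z_threshold = x$z_threshold
  )
}

#' Tidy a training run
#'
#' @param x a `tq_fit` from [train_toy()].
#' @param ... unused.
#' @return Long tibble: `step`, `component`, `loss`.
#' @export
tidy.tq_fit <- function(x, ...) {
  tidyr::pivot_longer(x$trace, -"step", names_to = "component",
                      values_to = "loss")
}

#' Glance at a training run
#' @param x a `tq_fit`.
#' @param ... unused.
#' @return One-row tibble: steps, final and best total loss, parameters.
#' @export
glance.tq_fit <- function(x, ...) {
  tibble::tibble(
    steps = nrow(x$trace),
    final_loss = utils::tail(x$trace$total, 1),
    best_loss = min(x$trace$total),
    n_parameters = n_parameters(x$network)
  )
}

#' Plot the training loss trace
#'
#' @param object a `tq_fit`.
#' @param ... unused.
#' @return A ggplot of the four loss components and their mean by step.
#' @export
autoplot.tq_fit <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$step, y = .data$loss, color = .data$component)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit
#'
#' @param object a `tq_calibration`.
#' @param ... unused.
#' @return A ggplot of visual vs computational scores, the no-intercept
#'   fit line, and flagged outliers.
#' @export
autoplot.tq_calibration <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$computational, y = .data$visual)
  ) +
    ggplot2::geom_abline(slope = object$k, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$inlier,
                                     color = .data$inlier)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(
      x = "computational score", y = "visual score",
      title = sprintf("no-intercept calibration, k = %.3f", object$k)
    ) +
    ggplot2::theme_minimal()
}

#' Plot tile informativeness over the slide grid
#'
#' @param object a tile-record tibble from [tile_and_rank()].
#' @param ... unused.
#' @return A ggplot heat map of informativeness with selected tiles
#'   outlined.
#' @export
plot_tile_ranking <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$grid_col, y = -.data$grid_row,
                 fill = .data$informativeness)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = object[object$selected, ],
      fill = NA, color = "red", linewidth = 0.4
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "grid column", y = "grid row",
                  fill = "informativeness") +
    ggplot2::theme_minimal()
}
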