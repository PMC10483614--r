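#' Plot a fitted count sigmoid
#'
#' Observed object counts with the fitted logistic overlaid; the halving
#' time (when defined) is marked with a dashed line.
#'
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  df <- object$series
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_days, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (days)", y = "objects per field",
                  subtitle = sprintf("n0 = %.1f, b = %.1f, t_m = %.1f d, s = %.2f d",
                                     object$n0, object$b, object$t_m, object$s))
  if (object$status %in% c("converged", "degenerate")) {
    tt <- seq(min(df$time_days), max(df$time_days), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(time_days = tt, count = predict_sigmoid(object, tt)),
      colour = "firebrick"
    )
  }
  if (is.finite(object$t_half %||% NA_real_)) {
    p <- p + ggplot2::geom_vline(xintercept = object$t_half,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a directionality scaling fit
#'
#' Halving time versus seeding density on log-log axes with the fitted
#' power law; the slope separates directed (flat) from random (slope -1)
#' aggregation.
#'
#' @param object A `directionality_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.directionality_fit <- function(object, ...) {
  ggplot2::ggplot(object$assays,
                  ggplot2::aes(x = .data$density, y = .data$t_half)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "seeding density (cells/mm^3)",
                  y = "halving time (days)",
                  subtitle = sprintf("beta = %.2f +/- %.2f (%s)",
                                     object$beta, object$beta_se, object$label))
}

#' Plot an exponential growth fit
#'
#' Projected area over time on a log2 axis with the fitted exponential.
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_fit <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$time_days, y = .data$area_um2)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble(
        time_days = object$series$time_days,
        area_um2 = object$A0 * 2^(object$series$time_days / object$tau)
      ),
      colour = "firebrick"
    ) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = "time (days)", y = "total projected area (um^2)",
                  subtitle = sprintf("tau = %.2f d, T_d = %.2f d",
                                     object$tau, object$T_d))
}

#' Display a class mask
#'
#' Background, bulk and protrusion classes as a filled raster.
#'
#' @param mask A [class_mask()].
#' @return A ggplot object.
#' @export
plot_mask <- function(mask) {
  stopifnot(inherits(mask, "class_mask"))
  df <- tidyr::expand_grid(x = seq_len(ncol(mask$labels)),
                           y = seq_len(nrow(mask$labels)))
  df$class <- factor(as.vector(mask$labels),
                     levels = c(0, 1, 2),
                     labels = c("background", "bulk", "protrusion"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(
      values = c(background = "black", bulk = "grey70",
                 protrusion = "orange"), drop = FALSE
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}
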