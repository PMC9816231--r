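#' Plot cross-validated AUC against candidate feature count
#'
#' @param object A `fet_selection` from [rfe_select()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fet_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$mean_auc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "number of selected features",
                  y = "mean cross-validated AUC",
                  title = "Recursive feature elimination") +
    ggplot2::theme_minimal()
}

#' Plot evaluation metrics with bootstrap confidence intervals
#'
#' @param object A `fet_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fet_evaluation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "estimate (95% bootstrap CI)") +
    ggplot2::theme_minimal()
}

#' Plot outer-split AUCs of a nested cross-validation
#'
#' @param object A `fet_nested_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fet_nested_cv <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$variant, y = .data$test_auc)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$split)),
                        size = 2) +
    ggplot2::labs(x = NULL, y = "outer-split test AUC", colour = "split") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a parametric image
#'
#' @param image A [parametric_image()].
#' @param z Slice index (default the middle slice).
#' @param mask Optional logical array; the mask outline is overlaid.
#' @return A ggplot.
#' @export
plot_parametric_slice <- function(image, z = NULL, mask = NULL) {
  stopifnot(inherits(image, "parametric_image"))
  d <- dim(image$data)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(image$data[, , z])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = image$kind) +
    ggplot2::labs(title = sprintf("%s map, slice z = %d", image$kind, z)) +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    dm <- df
    dm$m <- as.vector(mask[, , z])
    p <- p + ggplot2::geom_tile(
      data = dm[dm$m, , drop = FALSE],
      ggplot2::aes(x = .data$x, y = .data$y),
      fill = NA, colour = "red", linewidth = 0.2, inherit.aes = FALSE)
  }
  p
}
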