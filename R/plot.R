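#' Plot a phantom or real B-scan
#'
#' @param object A `bscan`.
#' @param box Optional box tibble drawn over the image.
#' @param ... Unused.
#' @return A ggplot object (grayscale raster, vitreous side up).
#' @export
autoplot.bscan <- function(object, box = NULL, ...) {
  img <- object$image
  df <- tidyr::expand_grid(row = seq_len(nrow(img)) - 1L,
                           col = seq_len(ncol(img)) - 1L)
  df$value <- as.vector(img)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
  if (!is.null(box) && nrow(box) > 0) {
    p <- p + ggplot2::annotate(
      "rect", xmin = box$x_start, xmax = box$x_end,
      ymin = box$y_start, ymax = box$y_end,
      colour = "cyan", fill = NA, linewidth = 0.6
    )
  }
  p
}

#' Plot a label mask
#'
#' @param object A [label_mask()].
#' @param ... Unused.
#' @return A ggplot object with one colour per class.
#' @export
autoplot.label_mask <- function(object, ...) {
  lv <- c("background", names(SUBLAYER_CLASSES), "total (in box)")
  df <- tidyr::expand_grid(row = seq_len(nrow(object)) - 1L,
                           col = seq_len(ncol(object)) - 1L)
  df$class <- factor(lv[as.vector(unclass(object)) + 1L], levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a per-layer Dice report
#'
#' Bar chart of per-layer mean Dice with standard-deviation whiskers.
#'
#' @param object A `dice_report` from [evaluate_segmentation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dice_report <- function(object, ...) {
  df <- object$summary
  df$layer <- factor(df$layer, levels = df$layer)
  ggplot2::ggplot(df, ggplot2::aes(.data$layer, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                   ymax = pmin(1, .data$mean + .data$sd)),
      width = 0.25
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Dice score") +
    ggplot2::theme_minimal()
}

#' Plot precision-recall curves of a detection evaluation
#'
#' @param object An `ap_result` from [average_precision()].
#' @param ... Unused.
#' @return A ggplot object, one curve per IoU threshold.
#' @export
autoplot.ap_result <- function(object, ...) {
  ggplot2::ggplot(object$pr_curves,
                  ggplot2::aes(.data$recall, .data$precision,
                               colour = factor(.data$iou_threshold))) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(colour = "IoU threshold") +
    ggplot2::theme_minimal()
}

#' Plot the training log of a fitted segmenter
#'
#' @param object A `pathaware_segmenter`.
#' @param ... Unused.
#' @return A ggplot object with training loss and validation Dice by epoch.
#' @export
autoplot.pathaware_segmenter <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_dice"),
                            names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal()
}
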