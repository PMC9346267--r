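#' Plot a ROC curve
#'
#' ROC curve in 1 - specificity / sensitivity coordinates with the
#' Youden-optimal operating point marked.
#'
#' @param object A `roc_result` from [roc_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- tidy(object)
  best <- tibble(
    fpr = 1 - object$specificity / 100,
    tpr = object$sensitivity / 100
  )
  ggplot2::ggplot(pts, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = best, ggplot2::aes(.data$fpr, .data$tpr), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf(
        "AUC = %.3f (%.3f-%.3f), cut-off = %.4g",
        object$auc, object$ci_low, object$ci_high, object$best_cutoff
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise CCC matrix
#'
#' Tile plot of the agreement between observer combinations, one facet per
#' measure, labeled with the CCC and its category.
#'
#' @param data Tibble from [pairwise_ccc()].
#' @return A ggplot object.
#' @export
plot_ccc_matrix <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$combo_a, .data$combo_b, fill = .data$ccc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f\n(%s)", .data$ccc, .data$category)
    ), size = 3) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::scale_fill_gradient(
      limits = c(0, 1), low = "white",
      high = "steelblue", name = "CCC"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Display a field image with detected cells
#'
#' Raster view of the RGB field with nucleus centroids overlaid, filled by
#' DAB-positivity. A quick visual check of segmentation and classification.
#'
#' @param image RGB array in `[0, white_point]`.
#' @param segmentation Optional list from [segment_field()].
#' @param white_point Intensity scale of `image` (default 255).
#' @return A ggplot object.
#' @export
plot_field <- function(image, segmentation = NULL, white_point = 255) {
  h <- dim(image)[1]
  w <- dim(image)[2]
  df <- expand.grid(row = seq_len(h), col = seq_len(w))
  df$fill <- grDevices::rgb(
    as.vector(image[, , 1]) / white_point,
    as.vector(image[, , 2]) / white_point,
    as.vector(image[, , 3]) / white_point
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::theme_void()
  if (!is.null(segmentation)) {
    cent <- label_centroids(segmentation$nucleus_labels)
    cent$positive <- unname(segmentation$positive[as.character(cent$label)])
    p <- p + ggplot2::geom_point(
      data = cent,
      ggplot2::aes(.data$col, .data$row, colour = .data$positive),
      shape = 1, size = 2
    ) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "red", `FALSE` = "blue"),
        name = "DAB+"
      )
  }
  p
}
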