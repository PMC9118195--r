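#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn iterative_roc `autoplot()` draws the ROC curve with one
#'   labelled point per truth threshold.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$points) +
    ggplot2::geom_text(
      data = object$points,
      ggplot2::aes(label = sprintf("θ=%g", .data$theta)),
      nudge_y = -0.04, size = 3
    ) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Iterative ROC (AUC %.3f ± %.3f)",
                      object$auc, object$auc_se)
    )
}

#' @describeIn cross_validate_logo `autoplot()` draws the confusion
#'   matrix as a tile plot with counts.
#' @param object A fitted object.
#' @param ... Unused.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("actual", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = "Predicted class", y = "Actual class",
      title = sprintf("LOGO-CV confusion (accuracy %.1f%%)",
                      100 * object$accuracy)
    )
}

#' @describeIn kmeans_segment `autoplot()` draws the cluster label image.
#' @param object A fitted object.
#' @param ... Unused.
#' @export
autoplot.msi_segmentation <- function(object, ...) {
  ggplot2::ggplot(object$labels,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = factor(.data$cluster))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(fill = "Cluster", title = sprintf("k-means segmentation (k = %d)",
                                                    object$k))
}

#' Plot an extracted ion image
#'
#' @param image Tibble from [ion_image()] (`x`, `y`, `intensity`).
#' @param title Plot title (e.g. the target m/z).
#' @return A ggplot object.
#' @export
plot_ion_image <- function(image, title = "Extracted ion image") {
  ggplot2::ggplot(image, ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = title)
}

#' Plot PCA scores coloured by class
#'
#' @param model A `pca_model`.
#' @param x The feature-matrix tibble to project.
#' @param colour_col Metadata column used for colouring.
#' @param pcs Two components to display.
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(model, x, colour_col = "class_label",
                            pcs = c(1, 2)) {
  sc <- pca_scores(model, x)
  sc$colour <- x[[colour_col]]
  evr <- model$explained_variance_ratio
  ggplot2::ggplot(sc, ggplot2::aes(
    x = .data[[paste0("PC", pcs[[1]])]],
    y = .data[[paste0("PC", pcs[[2]])]],
    colour = .data$colour
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", pcs[[1]], 100 * evr[[pcs[[1]]]]),
      y = sprintf("PC%d (%.1f%%)", pcs[[2]], 100 * evr[[pcs[[2]]]]),
      colour = colour_col
    )
}
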