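# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a feature-space projection
#'
#' Scatter of the two principal components from [project_2d()];
#' background superpixels cluster densely near the origin while
#' anomalous ones scatter towards the periphery.
#'
#' @param object a `patch_projection`.
#' @param colour optional vector (e.g. anomaly score or flag) mapped to
#'   point colour; recycled against the rows.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.patch_projection <- function(object, colour = NULL, ...) {
  df <- object$scores
  ev <- round(100 * object$explained_variance, 1)
  p <- if (is.null(colour)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
      ggplot2::geom_point(alpha = 0.6)
  } else {
    df$colour <- colour
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                     colour = .data$colour)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ev[1]),
                    y = sprintf("PC2 (%.1f%%)", ev[2])) +
    ggplot2::theme_minimal()
}

#' Plot VAE training curves
#'
#' Epoch-mean reconstruction, KL and total loss from the training
#' history.
#'
#' @param object a `benthic_vae`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.benthic_vae <- function(object, ...) {
  long <- tidyr::pivot_longer(object$loss_history,
                              c("recon", "kl", "loss"),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "per-patch loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class average precision
#'
#' @param object a `detection_eval` from [evaluate_detections()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.detection_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class, c("ap50", "ap50_95"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "average precision (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a scene with its boxes
#'
#' Renders the image raster with ground-truth (and optionally detection)
#' boxes overlaid; a quick visual check of the synthetic generator and
#' the weak annotations.
#'
#' @param scene a `scene_record`.
#' @param boxes optional annotation/detection tibble for this scene.
#' @return a ggplot.
#' @export
plot_scene <- function(scene, boxes = NULL) {
  img <- scene$image
  h <- dim(img)[1]; w <- dim(img)[2]
  raster <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  dim(raster) <- c(h, w)
  df <- scene$ground_truth
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = 0, xmax = w,
                               ymin = -h, ymax = 0) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::theme_void()
  add_rects <- function(p, d, col) {
    if (is.null(d) || !nrow(d)) return(p)
    p + ggplot2::geom_rect(
      data = d,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = -.data$y_max, ymax = -.data$y_min),
      colour = col, fill = NA, linewidth = 0.4)
  }
  p <- add_rects(p, df, "yellow")
  add_rects(p, boxes, "cyan")
}

#' Plot gridded detection density
#'
#' Tile map of [grid_density()] output: block colour is abundance
#' (individuals per square metre of imaged seafloor) per spatial block.
#'
#' @param grid tibble from [grid_density()].
#' @param cell_size block side in metres (for tile dimensions).
#' @return a ggplot.
#' @export
plot_grid_density <- function(grid, cell_size = 200) {
  ggplot2::ggplot(grid, ggplot2::aes(
    x = (.data$cell_x + 0.5) * cell_size,
    y = (.data$cell_y + 0.5) * cell_size,
    fill = .data$density_ind_m2)) +
    ggplot2::geom_tile(width = cell_size, height = cell_size) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)",
                  fill = expression("ind."~m^-2)) +
    ggplot2::theme_minimal()
}
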