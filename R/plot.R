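#' Boxplot of batch similarity metrics
#'
#' One box per metric (Dice, feature similarity, normalized Hausdorff) with
#' 1.5 x IQR whiskers and outliers as individual points — the standard way
#' batch agreement over a sample collection is displayed.
#'
#' @param object A tibble of stacked [evaluate_transfer()] rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @exportS3Method ggplot2::autoplot
autoplot.similarity_report <- function(object, ...) {
  plot_metric_boxplot(object)
}

#' @rdname autoplot.similarity_report
#' @param reports Any data frame with `dsc`, `feature_similarity` and
#'   `hausdorff_normalized` columns (stacking drops the report class, so
#'   this entry point takes plain tibbles too).
#' @export
plot_metric_boxplot <- function(reports) {
  long <- tidyr_pivot(reports)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.colour = "red",
                          fill = "grey90", width = 0.5) +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Agreement between transferred and manual annotations") +
    ggplot2::theme_minimal()
}

# minimal long-format reshape without a tidyr dependency
tidyr_pivot <- function(df) {
  metrics <- c(dsc = "Dice", feature_similarity = "Feature similarity",
               hausdorff_normalized = "Hausdorff (normalized)")
  parts <- lapply(names(metrics), function(m) {
    v <- df[[m]]
    keep <- !is.na(v)
    if (!any(keep)) return(NULL)
    tibble::tibble(metric = metrics[[m]], value = v[keep])
  })
  dplyr::bind_rows(parts)
}

#' Landmark residual plot for a fitted registration
#'
#' Shows the fixed-frame landmarks with arrows to the positions the fitted
#' transform predicts for their moving-frame partners; long arrows expose
#' badly picked pairs during the interactive refinement loop.
#'
#' @param points A [control_points()] object.
#' @param transform A `moving_to_fixed` [fit_transform()] result.
#' @return A ggplot object.
#' @export
plot_registration <- function(points, transform) {
  stopifnot(inherits(points, "control_points"),
            inherits(transform, "poly_transform"))
  pred <- evaluate_transform(transform, cbind(points$moving_x, points$moving_y))
  df <- tibble::tibble(x = points$fixed_x, y = points$fixed_y,
                       xend = pred[, 1], yend = pred[, 2],
                       residual = sqrt((pred[, 1] - points$fixed_x)^2 +
                                       (pred[, 2] - points$fixed_y)^2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          color = "red") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Landmark residuals of the fitted registration",
                  subtitle = sprintf("RMS residual %.2f px over %d pairs",
                                     attr(transform, "rms"),
                                     attr(transform, "n_pairs"))) +
    ggplot2::theme_minimal()
}

#' Display an image or mask with ggplot
#'
#' Convenience raster display in pixel coordinates (origin top-left, as in
#' image viewers).
#'
#' @param img Image array or 0/1 mask matrix.
#' @return A ggplot object.
#' @export
plot_image <- function(img) {
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  rast <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  dim(rast) <- dim(img)[1:2]
  df <- expand.grid(y = seq_len(nrow(rast)), x = seq_len(ncol(rast)))
  df$fill <- as.vector(rast)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
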