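# ggplot2 helpers for images, masks and feature tables.

#' Plot a gray image, optionally with a mask outline
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Optional binary matrix overlaid in translucent red.
#' @return A ggplot raster plot (row 1 at the top).
#' @export
plot_gray <- function(image, mask = NULL) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(image)), times = ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    value = as.vector(image)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
  if (!is.null(mask) && sum(mask) > 0) {
    dm <- df
    dm$on <- as.vector(mask) == 1
    p <- p + ggplot2::geom_raster(data = dm[dm$on, ],
                                  fill = "red", alpha = 0.35)
  }
  p
}

#' Feature-space scatter of a cohort feature table
#'
#' @param features Tibble from [run_pipeline()]'s `features` (needs a
#'   `label` column and at least two numeric feature columns).
#' @param x,y Names of the feature columns to plot (defaults: contrast
#'   and entropy of the HL subband, where the texture classes separate).
#' @return A ggplot scatter coloured by class.
#' @export
plot_features <- function(features, x = "HL_CN", y = "HL_ER") {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data[[x]], y = .data[[y]],
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "class")
}

#' @method autoplot ateo_cnn
#' @export
autoplot.ateo_cnn <- function(object, ...) {
  autoplot(object$fit) + ggplot2::labs(title = "classifier training (ATEO)",
                                       y = "training MSE")
}
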