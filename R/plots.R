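# ggplot2 autoplot methods and small plotting helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a grayscale image or binary mask
#'
#' @param img Numeric matrix.
#' @param title Optional plot title.
#' @return A ggplot raster plot (origin top-left, as images are viewed).
#' @export
plot_gray <- function(img, title = NULL) {
  stopifnot_gray(img)
  df <- tidyr::expand_grid(
    row = seq_len(nrow(img)), col = seq_len(ncol(img))
  )
  df$value <- as.vector(t(img))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
    fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "green") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_gray Autoplot of the size distribution: particle
#'   counts per 10-um radius bin.
#' @param object A `size_distribution` tibble.
#' @param ... Unused.
#' @export
autoplot.size_distribution <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    bin = factor(
      ifelse(
        is.infinite(.data$bin_hi),
        paste0(">", .data$bin_lo),
        paste0("[", .data$bin_lo, ",", .data$bin_hi, ")")
      ),
      levels = ifelse(
        is.infinite(object$bin_hi),
        paste0(">", object$bin_lo),
        paste0("[", object$bin_lo, ",", object$bin_hi, ")")
      )
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$count)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(
      x = "equivalent radius (µm)", y = "particles",
      title = "Aggregate size distribution"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Autoplot of a TV denoising trace
#'
#' Shows the total variation and the relative change per iteration on
#' free y scales.
#'
#' @param object A `tv_trace` tibble from [tv_denoise()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tv_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as.data.frame(object)[c("iteration", "tv", "rel_change")],
    c("tv", "rel_change"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL, title = "TV denoising") +
    ggplot2::theme_minimal()
}

#' Autoplot of an image result
#'
#' The final binary mask with particle centroids marked.
#'
#' @param object An `image_result` from [analyze_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.image_result <- function(object, ...) {
  p <- plot_gray(object$mask, title = paste0(
    object$n_particles, " particle(s), ", object$threshold$method
  ))
  if (object$n_particles > 0) {
    p <- p + ggplot2::geom_point(
      data = object$particles,
      ggplot2::aes(.data$centroid_col, .data$centroid_row),
      inherit.aes = FALSE, colour = "red", shape = 3
    )
  }
  p
}
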