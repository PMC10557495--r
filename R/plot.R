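#' Plot particles of a topology graph
#'
#' 2D projection of the particle cloud with graph edges, colored by particle
#' kind (for an `av_graph`) or by artery/vein class (for an
#' `av_labeled_graph`); point size tracks the particle scale.
#'
#' @param x an `av_graph` or `av_labeled_graph`.
#' @param plane projection plane: `"xz"` (default), `"xy"` or `"yz"`.
#' @return a ggplot object.
#' @export
plot_particles <- function(x, plane = c("xz", "xy", "yz")) {
  plane <- match.arg(plane)
  labeled <- inherits(x, "av_labeled_graph")
  graph <- if (labeled) x$graph else x
  pc <- if (labeled) x$particles else graph$particles
  ax <- strsplit(plane, "")[[1]]
  col <- if (labeled) "class" else "kind"
  seg <- dplyr::tibble(
    x0 = pc[[ax[1]]][graph$edges$from], y0 = pc[[ax[2]]][graph$edges$from],
    x1 = pc[[ax[1]]][graph$edges$to], y1 = pc[[ax[2]]][graph$edges$to])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          color = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = pc,
                        ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                     color = .data[[col]],
                                     size = .data$scale),
                        alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(0.3, 2.5)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(ax[1], "(voxels)"), y = paste(ax[2], "(voxels)"),
                  color = NULL, size = "scale (vox)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.av_graph <- function(object, ...) plot_particles(object, ...)

#' @export
autoplot.av_labeled_graph <- function(object, ...) plot_particles(object, ...)

#' @export
autoplot.av_classifier <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training cross-entropy") +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a volume
#'
#' @param vol an [av_volume()].
#' @param z slice index (default: middle).
#' @return a ggplot object.
#' @export
plot_volume_slice <- function(vol, z = NULL) {
  arr <- as_array3(vol)
  z <- z %||% ceiling(dim(arr)[3] / 2)
  sl <- arr[, , z]
  df <- tidyr_expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("slice z = %d", z)) +
    ggplot2::theme_minimal()
}

# expand.grid with x varying fastest, as a tibble (column order preserved)
tidyr_expand_grid <- function(x, y) {
  tibble::tibble(x = rep(x, times = length(y)), y = rep(y, each = length(x)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot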