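# ggplot2 views of the main result types.

#' Plot a channel of a multiplexed scene
#'
#' Raster view of one channel with cell centroids overlaid, coloured by
#' ground-truth class when available.
#'
#' @param object A `multiplex_scene`.
#' @param channel Channel name to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multiplex_scene <- function(object, channel = NULL, ...) {
  ch <- channel %||% dimnames(object$image$channels)[[3]][1]
  m <- object$image$channels[, , ch]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$intensity <- m[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = ch, x = NULL, y = NULL)
  if (!is.null(object$cells) && nrow(object$cells) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$cells,
      ggplot2::aes(x = .data$col + 1, y = .data$row + 1,
                   colour = .data$class),
      inherit.aes = FALSE, shape = 1, size = 3
    )
  }
  p
}

#' Plot fitted reduced moduli
#'
#' Histogram of moduli coloured by QC status, facetted by timepoint when
#' present.
#'
#' @param object A `hertz_fits` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hertz_fits <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$modulus_pa))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$modulus_pa,
                                        fill = .data$qc_status)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::labs(x = "Reduced modulus (Pa)", y = "Curves")
  if ("timepoint" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$timepoint))
  }
  p
}

#' Paired before/after plot
#'
#' Connected per-participant lines across timepoints, the standard view for
#' paired pre/post readouts.
#'
#' @param frame Tibble with columns `participant`, `timepoint`, `value`.
#' @param ylab Axis label for the value.
#' @return A ggplot object.
#' @export
plot_paired <- function(frame, ylab = "value") {
  ggplot2::ggplot(frame, ggplot2::aes(x = .data$timepoint, y = .data$value,
                                      group = .data$participant)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = ylab)
}
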