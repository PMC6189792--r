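#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_rect geom_raster
#'   labs theme_minimal scale_fill_viridis_c annotate
#' @export
ggplot2::autoplot

#' Plot a DNA-content histogram
#'
#' Bar plot of counts (or normalized counts) per bin center, optionally with
#' the gate windows shaded, mirroring the conventional presentation of
#' cell-cycle histograms.
#'
#' @param object A `cyto_histogram`.
#' @param gates Optional [phase_gates()] to overlay.
#' @param normalized Plot `normalized_count` instead of raw counts (requires
#'   [normalize_axes()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_histogram <- function(object, gates = NULL, normalized = FALSE,
                                    ...) {
  tbl <- as_tibble(object)
  ycol <- if (normalized) "normalized_count" else "count"
  ylab <- if (normalized) "fraction of cells" else "cell count"
  p <- ggplot(tbl, aes(x = .data$bin_center, y = .data[[ycol]]))
  if (!is.null(gates)) {
    gtbl <- tibble(
      phase = factor(names(gates), levels = c("G1", "S", "G2M")),
      lo = vapply(gates, `[`, numeric(1), 1),
      hi = vapply(gates, `[`, numeric(1), 2))
    p <- p + geom_rect(
      data = gtbl,
      aes(xmin = .data$lo, xmax = .data$hi, fill = .data$phase),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE)
  }
  p + geom_col(width = attr(object, "interval"), fill = "grey25") +
    labs(x = "integrated intensity (counts)", y = ylab) +
    theme_minimal()
}

#' Plot a rendered or acquired field
#'
#' @param object A `cyto_field`.
#' @param ... Unused.
#' @return A ggplot raster of pixel intensities.
#' @export
autoplot.cyto_field <- function(object, ...) {
  px <- object$pixels
  tbl <- tibble(row = as.vector(row(px)), col = as.vector(col(px)),
                value = as.vector(px))
  ggplot(tbl, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = "counts") +
    labs(x = "column (px)", y = "row (px)") +
    theme_minimal()
}

#' Plot an intensity surface
#'
#' Raster view of a block-maximum downsampled field (see
#' [intensity_surface()]); clipped nuclei appear as flat plateaus at the
#' detector maximum.
#'
#' @param surface Matrix from [intensity_surface()].
#' @return A ggplot object.
#' @export
plot_intensity_surface <- function(surface) {
  tbl <- tibble(row = as.vector(row(surface)), col = as.vector(col(surface)),
                value = as.vector(surface))
  ggplot(tbl, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = "block max\n(counts)") +
    labs(x = "block column", y = "block row") +
    theme_minimal()
}

#' Plot replicate phase fractions by condition
#'
#' @param stats Tibble from [replicate_stats()].
#' @return A ggplot bar chart with SD error bars when available.
#' @export
plot_phase_fractions <- function(stats) {
  p <- ggplot(stats, aes(x = .data$phase, y = 100 * .data$mean))
  if ("condition" %in% names(stats)) {
    p <- ggplot(stats, aes(x = .data$phase, y = 100 * .data$mean,
                           fill = .data$condition)) +
      ggplot2::geom_col(position = "dodge")
  } else {
    p <- p + geom_col(fill = "steelblue")
  }
  if (any(!is.na(stats$sd))) {
    pos <- if ("condition" %in% names(stats)) {
      ggplot2::position_dodge(width = 0.9)
    } else "identity"
    p <- p + ggplot2::geom_errorbar(
      aes(ymin = 100 * (.data$mean - .data$sd),
          ymax = 100 * (.data$mean + .data$sd)),
      width = 0.2, position = pos)
  }
  p + labs(x = NULL, y = "cells in phase (%)") + theme_minimal()
}
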