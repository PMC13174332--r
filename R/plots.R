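#' Plot a taxonomy's cell set composition
#'
#' Bar chart of cell set sizes per hierarchy level, colored by the coarsest
#' level, a quick visual check that the hierarchy partitions cells as
#' expected.
#'
#' @param object An `ait_taxonomy`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ait_taxonomy <- function(object, ...) {
  cs <- cellsets(object$hierarchy)
  cs$level <- factor(cs$level, levels = object$hierarchy$levels)
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$label, y = .data$n_cells)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~level, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = NULL, y = "cells",
                  title = sprintf("taxonomy '%s'", object$taxonomy_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot mapping scores and confidence
#'
#' Histogram of best-correlation scores, with bootstrap confidence overlaid
#' when present.
#'
#' @param object An `ait_mapping`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ait_mapping <- function(object, ...) {
  df <- tibble(score = object$score, confidence = object$confidence)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::labs(x = "best correlation", y = "query cells",
                  title = sprintf("%s mapping of %d cells",
                                  attr(object, "method"), nrow(df))) +
    ggplot2::theme_minimal()
  if (!all(is.na(df$confidence))) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$confidence)) +
      ggplot2::geom_point(alpha = 0.4, color = "steelblue") +
      ggplot2::labs(x = "best correlation", y = "bootstrap confidence",
                    title = sprintf("%s mapping of %d cells",
                                    attr(object, "method"), nrow(df))) +
      ggplot2::theme_minimal()
  }
  p
}

#' Plot the leaf dendrogram of a taxonomy
#'
#' Draws the centroid dendrogram (average linkage, correlation distance)
#' as a segment plot with leaves in stored order.
#'
#' @param taxonomy An `ait_taxonomy` with a dendrogram.
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "ait_taxonomy"))
  if (is.null(taxonomy$dendrogram)) abort("taxonomy has no dendrogram")
  segs <- dendro_segments(taxonomy$dendrogram)
  leaves <- dendrogram_leaves(taxonomy$dendrogram)
  ggplot2::ggplot(segs$segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_along(leaves), labels = leaves) +
    ggplot2::labs(x = NULL, y = "1 - Pearson correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

# recursive layout: leaves at integer x, internal nodes at child midpoints
dendro_segments <- function(tree, next_x = 1) {
  if (!is.null(tree$label)) {
    return(list(x = next_x, next_x = next_x + 1, height = 0,
                segments = tibble(x = numeric(), xend = numeric(),
                                  y = numeric(), yend = numeric())))
  }
  left <- dendro_segments(tree$children[[1]], next_x)
  right <- dendro_segments(tree$children[[2]], left$next_x)
  x <- (left$x + right$x) / 2
  h <- tree$height
  segs <- bind_rows(
    left$segments, right$segments,
    tibble(x = c(left$x, right$x, left$x),
           xend = c(left$x, right$x, right$x),
           y = c(left$height, right$height, h),
           yend = c(h, h, h))
  )
  list(x = x, next_x = right$next_x, height = h, segments = segs)
}
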