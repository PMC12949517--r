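# ggplot2 displays for the main result types

#' Volcano plot of a DEG table
#'
#' @param deg a [find_markers()] table.
#' @param label_top number of top DEGs to label (default 10).
#' @return a ggplot object.
#' @export
plot_volcano <- function(deg, label_top = 10) {
  deg <- dplyr::mutate(deg, neglog_q = -log10(pmax(.data$q_value, 1e-300)))
  top <- top_markers(deg, label_top, flagged_only = TRUE)
  ggplot2::ggplot(deg, ggplot2::aes(.data$log2_fold_change, .data$neglog_q)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_deg), size = 0.8) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$gene),
                       size = 2.5, vjust = -0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q",
                  title = sprintf("%s vs %s", deg$group_a[1], deg$group_b[1])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hipp_axis_profile <- function(object, ...) {
  ycol <- if ("z" %in% names(object)) "z" else "relative"
  ggplot2::ggplot(object, ggplot2::aes(.data$axis_mm, .data[[ycol]])) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "longitudinal coordinate (mm)", y = ycol,
                  title = attr(object, "entity")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hipp_homology <- function(object, ...) {
  df <- tidy.hipp_homology(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$type_b, .data$type_a,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10", limits = c(0, 1)) +
    ggplot2::labs(x = "species B type", y = "species A type",
                  fill = "co-clustering\nproportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' Spatial map of one segmented section
#'
#' @param map a `hipp_subregion_map`.
#' @param coords the section's x/y coordinates (microns), rows aligned with
#'   the map's cells.
#' @return a ggplot object.
#' @export
plot_section_map <- function(map, coords) {
  lab <- map$labels
  if (!is.null(map$annotation)) lab <- map$annotation[as.character(lab)]
  df <- tibble::tibble(x = coords[[1]], y = coords[[2]], subregion = factor(lab))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$subregion)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = map$section_id) +
    ggplot2::theme_minimal()
}
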