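#' Plot helpers
#'
#' ggplot2 views of the main result types: the MDS embedding of ATAC
#' samples, the distance-to-TSS profile, per-contrast accessibility
#' direction counts, and cell-composition bars.
#'
#' @param object,x Result object.
#' @param colour_by Optional sample-sheet tibble; samples are coloured by
#'   its `timepoint` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.atac_mds <- function(object, colour_by = NULL, ...) {
  df <- tidy(object)
  if (!is.null(colour_by)) {
    df <- left_join(df, colour_by, by = "sample")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          colour = .data$timepoint))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  }
  p + ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample), vjust = -1,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "MDS dim 1", y = "MDS dim 2",
                  title = "MDS of log2-CPM accessibility profiles") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.tss_profile <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$bin_start[1:2]),
                      fill = "steelblue") +
    ggplot2::labs(x = "distance to nearest TSS (bp)", y = "peaks",
                  subtitle = sprintf("%.1f%% within %d bp",
                                     100 * object$fraction_within,
                                     object$within)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param da_tables Named list of `da_table` objects.
#' @export
plot_da_directions <- function(da_tables, ...) {
  df <- purrr::imap_dfr(da_tables, function(d, nm) {
    g <- glance(d)
    tibble(contrast = nm,
           direction = c(paste("up in", g$group1), paste("up in", g$group2)),
           n = c(g$n_up_in_1, g$n_up_in_2))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$contrast, .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "differentially accessible peaks") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param comp Composition tibble from [composition()].
#' @param by Category column name.
#' @export
plot_composition <- function(comp, by = "cluster", ...) {
  ggplot2::ggplot(comp, ggplot2::aes(.data$timepoint, .data$fraction,
                                     fill = .data[[by]])) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(y = "share of cells") +
    ggplot2::theme_minimal()
}
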