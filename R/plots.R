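# ggplot2 views of the main result types.

#' Bar chart of DMR genomic locations against the array background
#'
#' @param location_table Tibble from [dmr_location_table()].
#' @return A ggplot.
#' @export
plot_dmr_locations <- function(location_table) {
  df <- dplyr::mutate(
    location_table,
    feature_class = factor(.data$feature_class, levels = region_precedence),
    set = factor(.data$set, levels = c("background", "all", "hypo", "hyper"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$pct, fill = .data$feature_class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "% of DMRs (or array probes)", fill = "Region") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bulk_deconvolution <- function(object, ...) {
  ggplot2::ggplot(
    object$proportions,
    ggplot2::aes(x = .data$sample_id, y = .data$proportion, fill = .data$cell_type)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Cell-type proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.spot_deconvolution <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(object$proportions, .data$sample_id, .data$cell_type),
    proportion = mean(.data$proportion), .groups = "drop"
  )
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$sample_id, y = .data$proportion, fill = .data$cell_type)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Mean topic proportion", fill = "Topic") +
    ggplot2::theme_minimal()
}

#' Hex-grid map of spot cluster labels
#'
#' @param labels A `spot_clustering` tibble.
#' @param positions Tibble with `sample_id`, `barcode`, `array_row`,
#'   `array_col` (e.g. bound from the datasets).
#' @return A ggplot, one facet per sample.
#' @export
plot_spot_clusters <- function(labels, positions) {
  df <- dplyr::inner_join(labels, positions, by = c("sample_id", "barcode"))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$array_col + .data$array_row / 2,
      y = -.data$array_row, colour = factor(.data$cluster)
    )
  ) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "Cluster") +
    ggplot2::theme_void()
}

#' Heatmap of significant interaction counts per directed cluster pair
#'
#' @param counts The `counts` tibble from [count_significant()].
#' @return A ggplot.
#' @export
plot_interaction_counts <- function(counts) {
  ggplot2::ggplot(
    counts,
    ggplot2::aes(x = .data$receiver_group, y = .data$sender_group, fill = .data$n)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = "Receiver", y = "Sender", fill = "Significant R-L") +
    ggplot2::theme_minimal()
}
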