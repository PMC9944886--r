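#' Plot a shape-match table
#'
#' Dot plot of the reported ligand pairs ranked by final Tanimoto, coloured
#' by the winning start family.
#'
#' @param object A `shape_match_table` from [all_vs_all_match()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_match_table
#' @export
autoplot.shape_match_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      pair = stats::reorder(paste(.data$query_id, "~",
                                                  .data$db_id),
                                            .data$tanimoto))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tanimoto, y = .data$pair,
                                   colour = .data$best_start_family)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "shape Tanimoto", y = NULL, colour = "start family") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of an affinity bin distribution
#'
#' @param binned Output of [bin_distribution()].
#' @param type Label for the measurement type (plot title).
#' @return A ggplot object.
#' @export
plot_affinity_bins <- function(binned, type = "Kd") {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "entries",
                  title = paste(type, "distribution")) +
    ggplot2::theme_minimal()
}
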