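# ggplot2 views of the main result types.  Scores use the heatmap palette
# of the field: red shades for active/up, green for inactive/down.

score_palette <- c("-3" = "#1b7837", "-2" = "#5aae61", "-1" = "#a6dba0",
                   "0" = "white", "1" = "#f4a582", "2" = "#d6604d",
                   "3" = "#b2182b")

#' Heatmap of a merged score matrix
#'
#' @param object a [merged_scores()] matrix.
#' @param row_order,col_order optional orderings (e.g. from [bicluster()]).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.merged_scores <- function(object, row_order = NULL,
                                   col_order = NULL, ...) {
  df <- tidy(object)
  df$protein <- factor(df$protein, levels = row_order %||%
                         rev(rownames(object)))
  df$sample <- factor(df$sample, levels = col_order %||% colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$protein,
                                   fill = factor(.data$score,
                                                 levels = -3:3))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = score_palette, name = "score",
                               drop = FALSE) +
    ggplot2::labs(x = "sample", y = "master regulator") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of a biclustering in dendrogram order
#'
#' @param object an `mr_biclustering` from [bicluster()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mr_biclustering <- function(object, ...) {
  autoplot(object$matrix, row_order = rev(object$row_order),
           col_order = object$col_order)
}

#' Feedback-selection plot: cosine with bootstrap CI per protein
#'
#' @param object a `feedback_records` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.feedback_records <- function(object, ...) {
  df <- dplyr::filter(object, .data$gene_measured)
  df$protein <- factor(df$protein,
                       levels = df$protein[order(df$cosine)])
  thr <- attr(object, "cos_threshold") %||% 0.3
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cosine, y = .data$protein,
                                   colour = .data$selected)) +
    ggplot2::geom_vline(xintercept = c(0, thr), linetype = c(1, 2),
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "cosine(state profile, DEG profile)", y = NULL,
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' State matrix heatmap
#'
#' @param object a [state_matrix()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.state_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$protein,
                                   fill = factor(.data$state,
                                                 levels = c(-1, 0, 1)))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c("-1" = "#1b7837", "0" = "white", "1" = "#b2182b"),
      name = "state", drop = FALSE,
      labels = c("inactive", "absent", "active")) +
    ggplot2::labs(x = "sample", y = "protein") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Null-versus-observed subnetwork connectivity plot
#'
#' @param null result of [random_subnetwork_null()].
#' @param observed_lcc observed largest-component size.
#' @return A ggplot object.
#' @export
plot_subnetwork_null <- function(null, observed_lcc) {
  ggplot2::ggplot(null$draws, ggplot2::aes(x = .data$lcc_size)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = observed_lcc, colour = "#b2182b") +
    ggplot2::labs(x = "largest connected component size (random draws)",
                  y = "draws") +
    ggplot2::theme_minimal()
}
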