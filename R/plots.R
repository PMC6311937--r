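#' Plot per-sequence silhouettes of a validity result
#'
#' Horizontal silhouette bars grouped and coloured by family, the standard
#' visual check of how well the distance structure separates the labeled
#' families; a dashed line marks the overall silhouette width.
#'
#' @param object An `aln_validity` object from [validity_scores()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aln_validity <- function(object, ...) {
  df <- object$silhouettes |>
    dplyr::arrange(.data$family, .data$silhouette) |>
    dplyr::mutate(id = factor(.data$id, levels = .data$id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$silhouette, y = .data$id,
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$sw, linetype = "dashed") +
    ggplot2::labs(
      x = "silhouette S(i)", y = NULL, fill = "family",
      title = sprintf("SW = %.6f, RS = %.6f (n = %d)", object$sw, object$rs,
                      object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a distance matrix as a heatmap
#'
#' @param object An [aln_dist] matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aln_dist <- function(object, ...) {
  ids <- rownames(object)
  df <- tidyr::expand_grid(id_a = ids, id_b = ids) |>
    dplyr::mutate(distance = as.vector(t(unclass(object))),
                  id_a = factor(.data$id_a, levels = ids),
                  id_b = factor(.data$id_b, levels = rev(ids)))
  ggplot2::ggplot(df, ggplot2::aes(.data$id_a, .data$id_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "dis") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar chart of mean validity scores per method and group
#'
#' Summarises a score table from [evaluate_group()] as the mean score over
#' resamples, one panel per score, bars grouped by benchmark group.
#'
#' @param scores Score table with columns `group`, `dataset`, `method`,
#'   `sw`, `rs`.
#' @param resamples_only Drop the `original` dataset rows before averaging?
#' @return A ggplot object.
#' @export
plot_score_summary <- function(scores, resamples_only = TRUE) {
  stopifnot(all(c("group", "dataset", "method", "sw", "rs") %in% names(scores)))
  df <- scores
  if (resamples_only) df <- dplyr::filter(df, .data$dataset != "original")
  df <- df |>
    tidyr::pivot_longer(c("sw", "rs"), names_to = "score",
                        values_to = "value") |>
    dplyr::group_by(.data$group, .data$method, .data$score) |>
    dplyr::summarise(mean_score = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(score = toupper(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean_score,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean score over resamples", fill = "method") +
    ggplot2::theme_minimal()
}
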