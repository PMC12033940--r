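#' Plot a propagation result
#'
#' Score-versus-rank curve with seed nodes highlighted: a quick visual check
#' that seed proximity dominates the prioritization.
#'
#' @param object A `propagation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot propagation_result
#' @export
autoplot.propagation_result <- function(object, ...) {
  df <- tidy(object) |> mutate(seed = .data$initial > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$final)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$seed), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "rank", y = "propagated score", colour = "seed",
      title = sprintf("Propagated scores: %s", object$network)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a candidate category profile
#'
#' Bar chart of candidate counts per functional category — the tabular twin
#' of a stacked classification bar.
#'
#' @param object A `category_profile` from [categorize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot category_profile
#' @export
autoplot.category_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$category, .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "candidates",
                  title = sprintf("Category profile (%d candidates)",
                                  attr(object, "n_candidates"))) +
    ggplot2::theme_minimal()
}

#' Plot a cross-condition candidate comparison
#'
#' Membership tile plot (node x condition), the tabular twin of a Venn
#' diagram: which candidates each condition selected at the compared top-k%.
#'
#' @param object A `candidate_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot candidate_comparison
#' @export
autoplot.candidate_comparison <- function(object, ...) {
  df <- object$membership |>
    tidyr::pivot_longer(-"node", names_to = "condition", values_to = "selected")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$node,
                                   fill = .data$selected)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "darkgreen")) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "selected",
      title = sprintf("Top %g%% candidate membership", object$k_percent)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot network metrics across conditions
#'
#' Faceted bar chart of the printed statistics (average degree, density,
#' clustering, modularity, diameter) for a set of networks.
#'
#' @param metrics_list A list of `network_metrics` objects.
#' @return A ggplot object.
#' @export
plot_metric_comparison <- function(metrics_list) {
  df <- bind_rows(lapply(metrics_list, glance)) |>
    tidyr::pivot_longer(
      c("average_degree", "density", "average_clustering", "modularity", "diameter"),
      names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
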