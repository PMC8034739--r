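#' Plot cluster variation-level profiles
#'
#' Line plot of each cluster's centroid variation levels across the three
#' periods, faceted by day type. The horizontal reference at 100 marks a
#' flat diurnal profile.
#'
#' @param object A `sed_cluster_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sed_cluster_model <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(
      dplyr::all_of(FEATURE_COLS),
      names_to = "feature", values_to = "variation_level"
    ) |>
    dplyr::mutate(
      day_type = ifelse(
        startsWith(.data$feature, "non_workday"), "non-workday", "workday"
      ),
      period = factor(
        sub(".*_(morning|afternoon|evening)$", "\\1", .data$feature),
        levels = PERIODS
      ),
      cluster = factor(.data$cluster)
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$period, y = .data$variation_level,
      group = .data$cluster, colour = .data$cluster
    )
  ) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~day_type) +
    ggplot2::labs(
      x = NULL, y = "variation level of sedentary time (%)",
      colour = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' Plot Ward merge costs
#'
#' Scree-style plot of the last merge-cost increments against the number of
#' clusters, the visual used to choose k from a dendrogram.
#'
#' @param object A `sed_ward_tree`.
#' @param k_max Largest number of clusters to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sed_ward_tree <- function(object, k_max = 10, ...) {
  n <- object$n_leaves
  ks <- seq_len(min(k_max, n - 1L))
  df <- tibble::tibble(
    k = ks,
    merge_cost = object$height[n - ks] # cost of collapsing k+1 -> k
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$merge_cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = ks) +
    ggplot2::labs(
      x = "number of clusters k",
      y = "within-SS increase when collapsing k+1 to k"
    ) +
    ggplot2::theme_minimal()
}

#' Plot participant-level diurnal profiles by cluster
#'
#' Spaghetti plot of individual variation-level profiles with the cluster
#' mean overlaid.
#'
#' @param features Feature tibble ([build_feature_matrix()] output).
#' @param assignments Tibble with `participant_id` and `cluster`.
#' @return A ggplot object.
#' @export
plot_variation_profiles <- function(features, assignments) {
  long <- features |>
    dplyr::inner_join(assignments, by = "participant_id") |>
    tidyr::pivot_longer(
      dplyr::all_of(FEATURE_COLS),
      names_to = "feature", values_to = "variation_level"
    ) |>
    dplyr::mutate(
      day_type = ifelse(
        startsWith(.data$feature, "non_workday"), "non-workday", "workday"
      ),
      period = factor(
        sub(".*_(morning|afternoon|evening)$", "\\1", .data$feature),
        levels = PERIODS
      ),
      cluster = factor(.data$cluster)
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$period, y = .data$variation_level)
  ) +
    ggplot2::geom_line(
      ggplot2::aes(group = .data$participant_id),
      alpha = 0.15
    ) +
    ggplot2::stat_summary(
      ggplot2::aes(group = .data$cluster, colour = .data$cluster),
      fun = mean, geom = "line", linewidth = 1
    ) +
    ggplot2::facet_grid(cluster ~ day_type) +
    ggplot2::labs(
      x = NULL, y = "variation level of sedentary time (%)"
    ) +
    ggplot2::theme_minimal()
}
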