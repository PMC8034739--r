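#' Tidy a fitted cluster model
#'
#' @param x A `sed_cluster_model`.
#' @param ... Unused.
#' @return Tibble with one row per cluster: `cluster`, `size`, `share`
#'   (proportion of participants), and the centroid coordinates.
#' @export
tidy.sed_cluster_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      cluster = seq_len(x$k),
      size = x$sizes,
      share = x$sizes / sum(x$sizes)
    ),
    tibble::as_tibble(x$centroids)
  )
}

#' @rdname tidy.sed_cluster_model
#' @return For `glance()`: a one-row tibble with `k`, `n`, `within_ss`,
#'   `iterations`.
#' @export
glance.sed_cluster_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = sum(x$sizes), within_ss = x$within_ss,
    iterations = x$iterations
  )
}

#' @rdname tidy.sed_cluster_model
#' @param data Feature tibble the model was fitted to.
#' @return For `augment()`: `data` with a `.cluster` column appended.
#' @export
augment.sed_cluster_model <- function(x, data, ...) {
  dplyr::mutate(data, .cluster = unname(x$assignments))
}

#' Tidy an ANOVA result
#'
#' @param x A `sed_anova`.
#' @param ... Unused.
#' @return Tibble of pairwise comparisons (`group1`, `group2`, `diff`,
#'   `p_raw`, `p_adj`).
#' @export
tidy.sed_anova <- function(x, ...) x$pairwise

#' @rdname tidy.sed_anova
#' @export
glance.sed_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$F, df_between = x$df_between, df_within = x$df_within,
    p_value = x$p
  )
}

#' Tidy a chi-square result
#'
#' @param x A `sed_chisq`.
#' @param ... Unused.
#' @return Tibble with one row per cell: observed, expected, adjusted
#'   residual, and flag.
#' @export
tidy.sed_chisq <- function(x, ...) {
  grid <- expand.grid(
    category = rownames(x$adjusted_residuals),
    cluster = colnames(x$adjusted_residuals),
    stringsAsFactors = FALSE
  )
  idx <- cbind(grid$category, grid$cluster)
  tibble::tibble(
    category = grid$category, cluster = grid$cluster,
    observed = x$observed[idx],
    expected = x$expected[idx],
    adjusted_residual = x$adjusted_residuals[idx],
    flagged = x$flags[idx]
  )
}

#' @rdname tidy.sed_chisq
#' @export
glance.sed_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = x$df, p_value = x$p)
}
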