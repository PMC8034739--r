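#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Classical one-way analysis of variance (F = MSB/MSW on k - 1 and N - k
#' degrees of freedom) followed by all pairwise two-sided t tests using the
#' pooled within-group mean square with N - k degrees of freedom, each p
#' multiplied by the number of pairs k(k-1)/2 and capped at 1 (the
#' Bonferroni convention of mainstream statistical packages).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @return A `sed_anova`: `F`, `df_between`, `df_within`, `p`, `pairwise`
#'   (tibble: `group1`, `group2`, `diff`, `p_adj`), `means`, `ns`.
#' @examples
#' res <- anova_oneway(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' res$p
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  ns <- table(groups)
  if (length(ns) < 2L) abort("need at least two groups")
  if (any(ns < 2L)) {
    abort(paste0(
      "group '", names(ns)[which(ns < 2L)[1]], "' has fewer than 2 observations"
    ))
  }
  fit <- stats::lm(values ~ groups)
  # perfect fits are handled explicitly below; silence lm's note about them
  an <- suppressWarnings(stats::anova(fit))
  means <- tapply(values, groups, mean)
  msw <- an["Residuals", "Mean Sq"]
  f <- an["groups", "F value"]
  p <- an["groups", "Pr(>F)"]
  total_ss <- an["groups", "Sum Sq"] + an["Residuals", "Sum Sq"]
  if (total_ss <= 1e-10 * max(1, mean(values)^2)) {
    f <- 0 # all observations identical: no variation to attribute
    p <- 1
    msw <- 0
  }
  new_sed_anova(
    f = f,
    df_between = an["groups", "Df"], df_within = an["Residuals", "Df"],
    p = p,
    means = as.numeric(means), ns = as.integer(ns),
    labels = names(ns), msw = msw
  )
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the identical one-way ANOVA (and Bonferroni post hoc tests)
#' that raw data matching the supplied group means, SDs, and sizes would
#' give: between-group SS from means and sizes, within-group SS as
#' `sum((n - 1) * sd^2)`.
#'
#' @param means,sds,ns Equal-length vectors of group means, SDs, and sizes
#'   (`ns >= 2`, `sds > 0`).
#' @param labels Optional group labels.
#' @return A `sed_anova` (see [anova_oneway()]).
#' @examples
#' anova_from_summary(c(64.8, 60.3, 59.3, 56.8), c(9.6, 9.9, 8.5, 8.8),
#'   c(107, 61, 19, 42))$p
#' @export
anova_from_summary <- function(means, sds, ns,
                               labels = as.character(seq_along(means))) {
  stopifnot(length(means) == length(sds), length(means) == length(ns))
  if (any(sds <= 0)) abort("all group SDs must be positive")
  if (any(ns < 2)) abort("all group sizes must be at least 2")
  k <- length(means)
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n_tot - k)
  f <- msb / msw
  new_sed_anova(
    f = f, df_between = k - 1L, df_within = n_tot - k,
    p = pf(f, k - 1, n_tot - k, lower.tail = FALSE),
    means = means, ns = as.integer(ns), labels = labels, msw = msw
  )
}

new_sed_anova <- function(f, df_between, df_within, p, means, ns, labels,
                          msw) {
  k <- length(means)
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(n_pairs), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    se <- sqrt(msw * (1 / ns[i1] + 1 / ns[i2]))
    praw <- if (se == 0) {
      if (abs(means[i1] - means[i2]) < 1e-12) 1 else 0
    } else {
      tval <- (means[i1] - means[i2]) / se
      2 * stats::pt(abs(tval), df_within, lower.tail = FALSE)
    }
    tibble::tibble(
      group1 = labels[i1], group2 = labels[i2],
      diff = means[i1] - means[i2],
      p_raw = praw, p_adj = min(1, praw * n_pairs)
    )
  })
  structure(
    list(
      F = f, df_between = df_between, df_within = df_within, p = p,
      pairwise = pw, means = setNames(means, labels),
      ns = setNames(as.integer(ns), labels), msw = msw
    ),
    class = "sed_anova"
  )
}

#' @export
print.sed_anova <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
    format(round(x$F, 3)), ", p = ", format_p(x$p), "\n", sep = "")
  sig <- x$pairwise[x$pairwise$p_adj < 0.05, ]
  if (nrow(sig) > 0) {
    cat("Bonferroni-significant pairs:",
      paste0(
        sig$group1, ifelse(sig$diff > 0, ">", "<"), sig$group2,
        collapse = ", "
      ), "\n")
  }
  invisible(x)
}

#' Pearson chi-square test with adjusted standardized residuals
#'
#' Plain Pearson chi-square test of independence (no continuity
#' correction), with per-cell adjusted standardized residuals
#' `(O - E) / sqrt(E (1 - row_total/N) (1 - col_total/N))`; cells with
#' `|residual| > 1.96` are flagged as driving the association.
#'
#' @param counts Matrix or table of non-negative integer counts
#'   (categories x clusters).
#' @return A `sed_chisq`: `chi2`, `df`, `p`, `expected`,
#'   `adjusted_residuals`, `flags`.
#' @examples
#' tab <- rbind(women = c(47, 24, 9, 29), men = c(60, 37, 10, 13))
#' chi_square_test(tab)$p
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("row", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("col", seq_len(ncol(counts)))
  }
  if (sum(counts) <= 0) abort("total count must be positive")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("every row and column margin must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  res <- ct$stdres
  structure(
    list(
      chi2 = unname(ct$statistic), df = unname(ct$parameter),
      p = ct$p.value, observed = counts, expected = ct$expected,
      adjusted_residuals = res, flags = abs(res) > 1.96
    ),
    class = "sed_chisq"
  )
}

#' @export
print.sed_chisq <- function(x, ...) {
  cat("Pearson chi-square: X2(", x$df, ") = ", format(round(x$chi2, 3)),
    ", p = ", format_p(x$p), "\n", sep = "")
  if (any(x$flags)) {
    idx <- which(x$flags, arr.ind = TRUE)
    cat("Cells with |adjusted residual| > 1.96:",
      paste0(
        rownames(x$flags)[idx[, 1]], "/", colnames(x$flags)[idx[, 2]],
        collapse = ", "
      ), "\n")
  }
  invisible(x)
}

# ANOVA for profiling tables: returns NULL (reported as NA) when the
# cluster structure cannot support the test (fewer than two clusters
# represented, or a cluster with fewer than two observations).
profiling_anova <- function(values, groups) {
  tb <- table(groups)
  if (length(tb) < 2L || any(tb < 2L)) return(NULL)
  anova_oneway(values, groups)
}

significant_pairs <- function(anova_res, alpha = 0.05) {
  sig <- anova_res$pairwise[anova_res$pairwise$p_adj < alpha, ]
  if (nrow(sig) == 0) return("")
  paste0(
    sig$group1, ifelse(sig$diff > 0, ">", "<"), sig$group2,
    collapse = ","
  )
}

#' Build cluster profile tables
#'
#' Characterizes clusters in the style of the standard results tables:
#' a characteristics table (categorical covariates: per-cluster counts and
#' percentages, chi-square p, adjusted-residual flags; continuous
#' covariates: per-cluster mean and SD, ANOVA p), a behavioral-metrics
#' table (objective measures by day type: mean and SD per cluster, ANOVA p,
#' significant Bonferroni pairs), and a domain table (self-reported domain
#' minutes by day type with per-variable listwise n).
#'
#' @param assignments Tibble with `participant_id` and `cluster` (integer or
#'   label).
#' @param covariates Optional covariate tibble (`participant_id` plus
#'   categorical character/factor and continuous numeric columns).
#' @param daytype_summary Optional [pool_daytype_metrics()] output.
#' @param domain_sb Optional long tibble of self-reported domain sedentary
#'   minutes: `participant_id`, `day_type`, `domain`, `minutes` (may contain
#'   `NA`; handled listwise per variable).
#' @param alpha Significance level for flags and pair reporting.
#' @return List of tibbles `characteristics`, `behavior`, `domains` (only
#'   those with inputs supplied), each carrying a numeric `p` column and a
#'   formatted `p_label`.
#' @export
build_profile_tables <- function(assignments, covariates = NULL,
                                 daytype_summary = NULL, domain_sb = NULL,
                                 alpha = 0.05) {
  assignments <- dplyr::mutate(
    assignments, cluster = as.character(.data$cluster)
  )
  clusters <- sort(unique(assignments$cluster))
  single <- length(clusters) < 2L
  out <- list()

  if (!is.null(covariates)) {
    dat <- dplyr::inner_join(assignments, covariates, by = "participant_id")
    vars <- setdiff(names(covariates), "participant_id")
    rows <- purrr::map_dfr(vars, function(v) {
      x <- dat[[v]]
      if (is.numeric(x)) {
        keep <- !is.na(x)
        stats_tbl <- tibble::tibble(
          variable = v, category = NA_character_,
          cluster = clusters,
          mean = as.numeric(tapply(x[keep], dat$cluster[keep], mean)),
          sd = as.numeric(tapply(x[keep], dat$cluster[keep], sd)),
          n = as.integer(table(dat$cluster[keep]))
        )
        res <- if (single) NULL else {
          profiling_anova(x[keep], dat$cluster[keep])
        }
        p <- if (is.null(res)) NA_real_ else res$p
        stats_tbl$p <- p
        stats_tbl$flag <- NA
        stats_tbl
      } else {
        keep <- !is.na(x)
        if (length(unique(x[keep])) < 2L) {
          inform(paste0(
            "covariate '", v, "' has a single level; chi-square skipped"
          ))
          return(tibble::tibble())
        }
        tab <- table(x[keep], dat$cluster[keep])
        chi <- if (single) NULL else chi_square_test(as.matrix(tab))
        prop <- prop.table(tab, margin = 2) * 100
        grid <- expand.grid(
          category = rownames(tab), cluster = colnames(tab),
          stringsAsFactors = FALSE
        )
        tibble::tibble(
          variable = v, category = grid$category, cluster = grid$cluster,
          n = as.integer(tab[cbind(grid$category, grid$cluster)]),
          pct = round(prop[cbind(grid$category, grid$cluster)], 1),
          p = if (single) NA_real_ else chi$p,
          flag = if (single) NA else {
            chi$flags[cbind(grid$category, grid$cluster)] &
              chi$adjusted_residuals[cbind(grid$category, grid$cluster)] > 0
          }
        )
      }
    })
    rows$p_label <- format_p(rows$p)
    out$characteristics <- rows
  }

  if (!is.null(daytype_summary)) {
    dat <- dplyr::inner_join(
      daytype_summary, assignments, by = "participant_id"
    )
    # per-day minutes for wear and SB; percentages from pooled minutes
    metrics <- c(
      "wear_min_day", "sb_min_day", "sb_pct", "breaks_per_sed_hour",
      "lipa_pct", "mvpa_pct"
    )
    combos <- tidyr::crossing(
      metric = metrics,
      day_type = intersect(c(DAY_TYPES, "overall"), unique(dat$day_type))
    )
    rows <- purrr::pmap_dfr(combos, function(metric, day_type) {
      sub <- dat[dat$day_type == day_type & dat$scope == "whole_day", ]
      vals <- sub[[metric]]
      keep <- !is.na(vals)
      res <- if (single) NULL else {
        profiling_anova(vals[keep], sub$cluster[keep])
      }
      tibble::tibble(
        metric = metric, day_type = day_type, cluster = clusters,
        mean = as.numeric(tapply(vals[keep], sub$cluster[keep], mean))[
          match(clusters, sort(unique(sub$cluster[keep])))
        ],
        sd = as.numeric(tapply(vals[keep], sub$cluster[keep], sd))[
          match(clusters, sort(unique(sub$cluster[keep])))
        ],
        p = if (is.null(res)) NA_real_ else res$p,
        significant_pairs =
          if (is.null(res)) "" else significant_pairs(res, alpha)
      )
    })
    rows$p_label <- format_p(rows$p)
    out$behavior <- rows
  }

  if (!is.null(domain_sb)) {
    dat <- dplyr::inner_join(domain_sb, assignments, by = "participant_id")
    combos <- dplyr::distinct(dat, .data$domain, .data$day_type)
    rows <- purrr::pmap_dfr(combos, function(domain, day_type) {
      sub <- dat[dat$domain == domain & dat$day_type == day_type, ]
      keep <- !is.na(sub$minutes) # listwise per variable
      res <- if (single) NULL else {
        profiling_anova(sub$minutes[keep], sub$cluster[keep])
      }
      tibble::tibble(
        domain = domain, day_type = day_type, cluster = clusters,
        n_listwise = sum(keep),
        mean = as.numeric(tapply(sub$minutes[keep], sub$cluster[keep], mean))[
          match(clusters, sort(unique(sub$cluster[keep])))
        ],
        sd = as.numeric(tapply(sub$minutes[keep], sub$cluster[keep], sd))[
          match(clusters, sort(unique(sub$cluster[keep])))
        ],
        p = if (is.null(res)) NA_real_ else res$p,
        significant_pairs =
          if (is.null(res)) "" else significant_pairs(res, alpha)
      )
    })
    rows$p_label <- format_p(rows$p)
    out$domains <- rows
  }
  out
}
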