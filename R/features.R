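#' Pool valid days into a day-type summary
#'
#' Aggregates a participant's valid days of one day type. Under the default
#' `"pooled"` convention, minutes are summed across contributing days per
#' scope and percentages are computed from the pooled minutes
#' (wear-weighted); under `"mean_of_days"` the per-day percentages are
#' averaged with equal weight. Only period-valid days contribute, so the
#' whole-day scope is exactly the sum of the period scopes.
#'
#' @param day_metrics Day-metrics tibble ([compute_day_metrics()]), any
#'   number of participants.
#' @param method Pooling convention, `"pooled"` (default) or
#'   `"mean_of_days"`.
#' @return Tibble, one row per participant, day type, and scope:
#'   pooled minutes, percentages, break rate, and `n_days_pooled`.
#' @examples
#' # two days, wear 600/300 min at 60%/90% sedentary -> pooled 70%
#' dm <- tibble::tibble(
#'   participant_id = "a", date = as.Date("2014-06-02") + 0:1,
#'   day_type = "workday", scope = "whole_day",
#'   wear_min = c(600, 300), sb_min = c(360, 270),
#'   lipa_min = c(240, 30), mvpa_min = c(0, 0),
#'   sb_pct = c(60, 90), lipa_pct = c(40, 10), mvpa_pct = c(0, 0),
#'   breaks = c(50L, 20L), breaks_per_sed_hour = c(50 / 6, 20 / 4.5),
#'   valid_day = TRUE, period_valid = TRUE
#' )
#' pool_daytype_metrics(dm)$sb_pct
#' @export
pool_daytype_metrics <- function(day_metrics,
                                 method = c("pooled", "mean_of_days")) {
  method <- match.arg(method)
  pooled <- day_metrics |>
    dplyr::filter(.data$period_valid) |>
    dplyr::group_by(.data$participant_id, .data$day_type, .data$scope) |>
    dplyr::summarise(
      n_days_pooled = dplyr::n(),
      mean_sb_pct = mean(.data$sb_pct),
      mean_lipa_pct = mean(.data$lipa_pct),
      mean_mvpa_pct = mean(.data$mvpa_pct),
      wear_min = sum(.data$wear_min),
      sb_min = sum(.data$sb_min),
      lipa_min = sum(.data$lipa_min),
      mvpa_min = sum(.data$mvpa_min),
      breaks = sum(.data$breaks),
      .groups = "drop"
    )
  if (method == "pooled") {
    pooled <- pooled |>
      dplyr::mutate(
        sb_pct = 100 * .data$sb_min / .data$wear_min,
        lipa_pct = 100 * .data$lipa_min / .data$wear_min,
        mvpa_pct = 100 * .data$mvpa_min / .data$wear_min
      )
  } else {
    pooled <- pooled |>
      dplyr::rename(
        sb_pct = "mean_sb_pct", lipa_pct = "mean_lipa_pct",
        mvpa_pct = "mean_mvpa_pct"
      )
  }
  pooled |>
    dplyr::mutate(
      breaks_per_sed_hour = ifelse(
        .data$sb_min > 0, .data$breaks / (.data$sb_min / 60), NA_real_
      )
    ) |>
    dplyr::mutate(
      wear_min_day = .data$wear_min / .data$n_days_pooled,
      sb_min_day = .data$sb_min / .data$n_days_pooled
    ) |>
    dplyr::select(
      "participant_id", "day_type", "scope", "n_days_pooled",
      "wear_min", "sb_min", "lipa_min", "mvpa_min",
      "wear_min_day", "sb_min_day",
      "sb_pct", "lipa_pct", "mvpa_pct", "breaks", "breaks_per_sed_hour"
    )
}

#' Pool all valid days regardless of day type
#'
#' Computes whole-day "overall" summaries per participant from every valid
#' day (workdays and non-workdays together), for profiling tables.
#'
#' @inheritParams pool_daytype_metrics
#' @return Tibble shaped like [pool_daytype_metrics()] output with
#'   `day_type = "overall"` and `scope = "whole_day"`.
#' @export
pool_overall_metrics <- function(day_metrics) {
  day_metrics |>
    dplyr::filter(.data$valid_day, .data$scope == "whole_day") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      day_type = "overall", scope = "whole_day",
      n_days_pooled = dplyr::n(),
      wear_min = sum(.data$wear_min), sb_min = sum(.data$sb_min),
      lipa_min = sum(.data$lipa_min), mvpa_min = sum(.data$mvpa_min),
      breaks = sum(.data$breaks),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sb_pct = 100 * .data$sb_min / .data$wear_min,
      lipa_pct = 100 * .data$lipa_min / .data$wear_min,
      mvpa_pct = 100 * .data$mvpa_min / .data$wear_min,
      breaks_per_sed_hour = ifelse(
        .data$sb_min > 0, .data$breaks / (.data$sb_min / 60), NA_real_
      )
    ) |>
    dplyr::mutate(
      wear_min_day = .data$wear_min / .data$n_days_pooled,
      sb_min_day = .data$sb_min / .data$n_days_pooled
    ) |>
    dplyr::select(
      "participant_id", "day_type", "scope", "n_days_pooled",
      "wear_min", "sb_min", "lipa_min", "mvpa_min",
      "wear_min_day", "sb_min_day",
      "sb_pct", "lipa_pct", "mvpa_pct", "breaks", "breaks_per_sed_hour"
    )
}

#' Diurnal variation level of sedentary time
#'
#' The variation level of a time period is the period's sedentary
#' percentage of wear time expressed relative to the whole day:
#' `100 * sb_pct_period / sb_pct_day`. A flat diurnal profile gives 100 in
#' every period.
#'
#' @param sb_pct_period Sedentary % of wear in the period.
#' @param sb_pct_day Sedentary % of wear over the whole day (> 0).
#' @return Variation level in percent.
#' @examples
#' variation_level(70, 56) # 125
#' @export
variation_level <- function(sb_pct_period, sb_pct_day) {
  if (any(is.na(sb_pct_day)) || any(sb_pct_day <= 0)) {
    abort("whole-day sedentary percentage must be positive; feature undefined")
  }
  100 * sb_pct_period / sb_pct_day
}

#' Compute the six variation-level features per participant
#'
#' From pooled day-type summaries, computes the workday and non-workday
#' morning/afternoon/evening variation levels. Participants with an
#' undefined feature (no sedentary time in a day type, or a missing day
#' type) are dropped with a message; the number dropped is recorded in the
#' `n_dropped` attribute.
#'
#' @param daytype_summary Output of [pool_daytype_metrics()].
#' @return Tibble: `participant_id` (sorted) plus the six feature columns
#'   `workday_morning` ... `non_workday_evening`.
#' @export
build_feature_matrix <- function(daytype_summary) {
  wide <- daytype_summary |>
    dplyr::select(
      "participant_id", "day_type", "scope", "sb_pct"
    ) |>
    tidyr::pivot_wider(
      names_from = c("day_type", "scope"), values_from = "sb_pct",
      names_sep = "_"
    )
  needed_day <- paste0(DAY_TYPES, "_whole_day")
  needed <- c(needed_day, FEATURE_COLS)
  for (col in setdiff(needed, names(wide))) wide[[col]] <- NA_real_
  ok <- stats::complete.cases(wide[needed]) &
    wide[[needed_day[1]]] > 0 & wide[[needed_day[2]]] > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(paste0(
      n_dropped, " participant(s) dropped: undefined variation-level feature"
    ))
  }
  out <- wide[ok, ]
  for (dt in DAY_TYPES) {
    for (p in PERIODS) {
      out[[paste0(dt, "_", p)]] <- variation_level(
        out[[paste0(dt, "_", p)]], out[[paste0(dt, "_whole_day")]]
      )
    }
  }
  out <- out |>
    dplyr::select("participant_id", dplyr::all_of(FEATURE_COLS)) |>
    dplyr::arrange(.data$participant_id)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Extract the numeric feature matrix
#'
#' @param features Tibble from [build_feature_matrix()] (or
#'   [generate_feature_cohort()]'s `features`).
#' @return Numeric matrix, rows named by participant id, columns in the
#'   fixed feature order.
#' @export
feature_matrix <- function(features) {
  m <- as.matrix(features[FEATURE_COLS])
  rownames(m) <- features$participant_id
  m
}
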