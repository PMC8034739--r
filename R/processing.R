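#' Classify epoch intensity from METs
#'
#' Standard METs cut-points: sedentary behavior (SB) at <= 1.5 METs, light
#' activity (LIPA) above 1.5 and below 3.0 METs, moderate-to-vigorous
#' activity (MVPA) at >= 3.0 METs. Intended for wear epochs; the caller is
#' responsible for masking non-wear time.
#'
#' @param mets Numeric vector of METs values (>= 0).
#' @return Character vector: `"SB"`, `"LIPA"`, or `"MVPA"`.
#' @examples
#' classify_intensity(c(1.5, 2.99, 3.0))
#' @export
classify_intensity <- function(mets) {
  if (any(mets < 0, na.rm = TRUE)) abort("METs values must be non-negative")
  dplyr::case_when(
    mets <= 1.5 ~ "SB",
    mets < 3.0 ~ "LIPA",
    TRUE ~ "MVPA"
  )
}

# Non-wear mask for one contiguous minute series: the union of all windows
# of >= 60 epochs in which every epoch is <= 0.9 METs except for at most two
# tolerated epochs in (0.9, 1.0]; any epoch > 1.0 breaks a window. Tolerated
# epochs count toward window length and toward non-wear minutes. O(n) via
# two monotone pointers (next terminator, position of the third tolerated
# epoch at or after each start).
nonwear_mask_vector <- function(mets, min_len = 60L, allowance = 2L) {
  n <- length(mets)
  if (n == 0L) return(logical(0))
  hard <- mets > 1.0
  tol <- mets > 0.9 & mets <= 1.0
  nxt_hard <- rev(cummin(rev(ifelse(hard, seq_len(n), n + 1L))))
  tol_pos <- which(tol)
  cum_tol <- c(0L, cumsum(tol))
  rank_cut <- cum_tol[seq_len(n)] + allowance + 1L # (allowance+1)-th tol >= i
  pos_cut <- rep(n + 1L, n)
  ok <- rank_cut <= length(tol_pos)
  pos_cut[ok] <- tol_pos[rank_cut[ok]]
  window_end <- pmin(nxt_hard, pos_cut) - 1L
  len <- window_end - seq_len(n) + 1L
  starts <- which(len >= min_len)
  cover <- logical(n)
  if (length(starts) > 0L) {
    d <- tabulate(starts, n + 1L) - tabulate(window_end[starts] + 1L, n + 1L)
    cover <- cumsum(d)[seq_len(n)] > 0L
  }
  cover
}

#' Detect non-wear time in minute-epoch series
#'
#' Marks intervals of at least 60 consecutive minutes of no activity
#' (METs <= 0.9), with an allowance of up to two minutes of limited
#' movement (METs <= 1.0) inside such an interval; any epoch above 1.0 METs
#' terminates a candidate interval. Intervals are extended to maximal
#' length, and tolerated minutes are included in the marked non-wear time.
#' Detection runs per participant over each maximal run of contiguous
#' (1-minute-spaced) timestamps, so device-off periods spanning midnight are
#' found.
#'
#' @param epochs Tibble with `participant_id`, `timestamp` (POSIXct, minute
#'   resolution), `mets`.
#' @return The input tibble, sorted by participant and time, with a logical
#'   `nonwear` column added.
#' @examples
#' ep <- tibble::tibble(
#'   participant_id = "a",
#'   timestamp = as.POSIXct("2014-06-02 00:00", tz = "UTC") + 0:69 * 60,
#'   mets = rep(0.5, 70)
#' )
#' sum(detect_nonwear(ep)$nonwear)
#' @export
detect_nonwear <- function(epochs) {
  if (any(epochs$mets < 0, na.rm = TRUE)) {
    abort("METs values must be non-negative")
  }
  epochs |>
    dplyr::arrange(.data$participant_id, .data$timestamp) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      .segment = cumsum(c(
        0, as.numeric(diff(.data$timestamp), units = "mins") != 1
      ))
    ) |>
    dplyr::group_by(.data$participant_id, .data$.segment) |>
    dplyr::mutate(nonwear = nonwear_mask_vector(.data$mets)) |>
    dplyr::ungroup() |>
    dplyr::select(-".segment")
}

#' Count sedentary breaks
#'
#' A sedentary break is a transition from a wear sedentary epoch directly to
#' a wear non-sedentary epoch (the start of a non-sedentary bout between
#' sedentary bouts). Transitions into or out of non-wear time do not count.
#' When a scope is given, a break is counted if its non-sedentary epoch lies
#' in scope.
#'
#' @param intensity Character vector of epoch intensities (`"SB"`, `"LIPA"`,
#'   `"MVPA"`) for a contiguous minute sequence.
#' @param nonwear Logical vector, `TRUE` where the device was not worn.
#' @param in_scope Logical vector, `TRUE` for epochs inside the counting
#'   window (clock scope).
#' @return Integer count.
#' @examples
#' count_breaks(c("SB", "SB", "LIPA", "SB", "MVPA"))
#' @export
count_breaks <- function(intensity, nonwear = rep(FALSE, length(intensity)),
                         in_scope = rep(TRUE, length(intensity))) {
  n <- length(intensity)
  if (n < 2L) return(0L)
  i <- seq_len(n - 1L)
  sum(
    !nonwear[i] & !nonwear[i + 1L] &
      intensity[i] == "SB" & intensity[i + 1L] != "SB" &
      in_scope[i + 1L]
  )
}

scope_bounds <- function(scope) {
  if (scope == "whole_day") c(MINUTES_DAY_START, MINUTES_DAY_END)
  else PERIOD_BOUNDS[[scope]]
}

#' Summarize one participant-day of epochs
#'
#' Computes wear, sedentary, light, and MVPA minutes and percentages of
#' wear, sedentary break counts and break rate, per scope: the whole
#' analysis day `[06:00, 24:00)` and the three periods morning
#' `[06:00, 12:00)`, afternoon `[12:00, 18:00)`, evening `[18:00, 24:00)`.
#' Epochs before 06:00 contribute non-wear context only. A day is valid
#' with >= 600 wear minutes in the analysis window; it is period-valid if
#' additionally each period has >= 90 wear minutes (25% of the 6-hour
#' period). Percentages are `NA` (flagged, not zero) where a scope has no
#' wear time; the break rate is `NA` where a scope has no sedentary time.
#'
#' @param day_epochs Tibble of one participant's epochs for one calendar
#'   date, with `timestamp`, `mets`, and `nonwear` columns.
#' @param day_type `"workday"` or `"non_workday"`.
#' @return Tibble with one row per scope (day-level metrics in long form).
#' @export
summarize_day <- function(day_epochs, day_type) {
  m <- minute_of_day(day_epochs$timestamp)
  wear <- !day_epochs$nonwear
  intensity <- classify_intensity(day_epochs$mets)
  rows <- purrr::map_dfr(SCOPES, function(scope) {
    b <- scope_bounds(scope)
    sel <- wear & m >= b[1] & m < b[2]
    wear_min <- sum(sel)
    sb_min <- sum(sel & intensity == "SB")
    lipa_min <- sum(sel & intensity == "LIPA")
    mvpa_min <- sum(sel & intensity == "MVPA")
    breaks <- count_breaks(
      intensity, day_epochs$nonwear,
      in_scope = m >= b[1] & m < b[2]
    )
    tibble::tibble(
      scope = scope,
      wear_min = wear_min, sb_min = sb_min,
      lipa_min = lipa_min, mvpa_min = mvpa_min,
      sb_pct = if (wear_min > 0) 100 * sb_min / wear_min else NA_real_,
      lipa_pct = if (wear_min > 0) 100 * lipa_min / wear_min else NA_real_,
      mvpa_pct = if (wear_min > 0) 100 * mvpa_min / wear_min else NA_real_,
      breaks = as.integer(breaks),
      breaks_per_sed_hour =
        if (sb_min > 0) breaks / (sb_min / 60) else NA_real_
    )
  })
  wd_wear <- rows$wear_min[rows$scope == "whole_day"]
  valid_day <- wd_wear >= 600
  period_valid <- valid_day &&
    all(rows$wear_min[rows$scope != "whole_day"] >= 90)
  rows |>
    dplyr::mutate(
      day_type = day_type, valid_day = valid_day,
      period_valid = period_valid, .before = 1
    )
}

#' Compute validated per-day metrics for a cohort
#'
#' Runs non-wear detection (if not already present), joins the day-type
#' diary, and summarizes every participant-date.
#'
#' @param epochs Epoch tibble (`participant_id`, `timestamp`, `mets`, and
#'   optionally `nonwear`).
#' @param diary Tibble with `participant_id`, `date`, `day_type`.
#' @return Tibble of day metrics, one row per participant-date-scope, with
#'   `participant_id`, `date`, `day_type`, validity flags, and the metric
#'   columns of [summarize_day()].
#' @export
compute_day_metrics <- function(epochs, diary) {
  if (!"nonwear" %in% names(epochs)) epochs <- detect_nonwear(epochs)
  epochs <- dplyr::mutate(
    epochs, date = as.Date(.data$timestamp, tz = "UTC")
  )
  key <- dplyr::distinct(epochs, .data$participant_id, .data$date)
  missing <- dplyr::anti_join(key, diary, by = c("participant_id", "date"))
  if (nrow(missing) > 0) {
    abort(paste0(
      "no diary entry for participant ", missing$participant_id[1],
      " on ", missing$date[1]
    ))
  }
  epochs |>
    dplyr::inner_join(diary, by = c("participant_id", "date")) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::group_modify(
      ~ summarize_day(.x, day_type = .x$day_type[1])
    ) |>
    dplyr::ungroup()
}

#' Assess accelerometer eligibility per participant
#'
#' A participant is eligible with at least 4 valid days including at least
#' 3 valid workdays and 1 valid non-workday, where additionally at least 3
#' workdays and 1 non-workday are period-valid (adequate wear in each of the
#' morning, afternoon, and evening periods).
#'
#' @param day_metrics Output of [compute_day_metrics()] (or any tibble with
#'   `participant_id`, `date`, `day_type`, `scope`, `valid_day`,
#'   `period_valid`).
#' @return Tibble: `participant_id`, day counts, `eligible`, and a `reasons`
#'   string listing each failed criterion (empty when eligible).
#' @export
assess_eligibility <- function(day_metrics) {
  day_metrics |>
    dplyr::filter(.data$scope == "whole_day") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_valid_days = sum(.data$valid_day),
      n_valid_workdays = sum(.data$valid_day & .data$day_type == "workday"),
      n_valid_nonworkdays =
        sum(.data$valid_day & .data$day_type == "non_workday"),
      n_period_valid_workdays =
        sum(.data$period_valid & .data$day_type == "workday"),
      n_period_valid_nonworkdays =
        sum(.data$period_valid & .data$day_type == "non_workday"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      eligible = .data$n_valid_days >= 4 &
        .data$n_valid_workdays >= 3 & .data$n_valid_nonworkdays >= 1 &
        .data$n_period_valid_workdays >= 3 &
        .data$n_period_valid_nonworkdays >= 1,
      reasons = purrr::pmap_chr(
        list(
          .data$n_valid_days, .data$n_valid_workdays,
          .data$n_valid_nonworkdays, .data$n_period_valid_workdays,
          .data$n_period_valid_nonworkdays
        ),
        function(nv, nw, nn, pw, pn) {
          r <- c(
            if (nv < 4) "fewer than 4 valid days",
            if (nw < 3) "fewer than 3 valid workdays",
            if (nn < 1) "no valid non-workday",
            if (pw < 3) "fewer than 3 period-valid workdays",
            if (pn < 1) "no period-valid non-workday"
          )
          paste(r, collapse = "; ")
        }
      )
    )
}
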