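#' Define a diurnal sedentary-behavior archetype
#'
#' An archetype is the generative description of one behavioral typology:
#' the mean and SD of its six diurnal variation levels (workday and
#' non-workday by morning/afternoon/evening), the day-level sedentary
#' percentage of wear time per day type, and the bout parameters used by the
#' epoch-level simulator. The period-specific sedentary propensity
#' (fraction of wear time) is derived as
#' `sb_target = (day SB% / 100) * (variation level / 100)`, so a cohort
#' simulated from an archetype reproduces its variation-level profile after
#' full epoch processing.
#'
#' @param name Archetype label.
#' @param vl_mean Named numeric vector of six variation-level means (%), in
#'   the order `workday_morning, workday_afternoon, workday_evening,
#'   non_workday_morning, non_workday_afternoon, non_workday_evening`.
#' @param vl_sd Named numeric vector of six between-person variation-level
#'   SDs (%), same order.
#' @param day_sb_pct Numeric length-2 vector: day-level sedentary percentage
#'   of wear time on workdays and non-workdays.
#' @param sb_target Optional named 6-vector of period sedentary fractions of
#'   wear, overriding the derivation from `day_sb_pct` and `vl_mean`.
#' @param sb_sd Between-person SD of the period sedentary fraction
#'   (recycled to length 6).
#' @param mean_bout_sed Mean sedentary bout length, minutes. Its reciprocal
#'   sets the sedentary-break rate: breaks/sedentary hour = 60 / bout length.
#' @param mvpa_share Fraction of non-sedentary wear minutes at >= 3.0 METs.
#'
#' @return An object of class `sed_archetype`.
#' @examples
#' a <- archetype_profile(
#'   "flat", vl_mean = rep(100, 6), vl_sd = rep(8, 6),
#'   day_sb_pct = c(60, 60)
#' )
#' a$sb_target
#' @export
archetype_profile <- function(name, vl_mean, vl_sd, day_sb_pct,
                              sb_target = NULL, sb_sd = 0.08,
                              mean_bout_sed = 7, mvpa_share = 0.17) {
  vl_mean <- setNames(as.numeric(vl_mean), FEATURE_COLS)
  vl_sd <- setNames(as.numeric(vl_sd), FEATURE_COLS)
  stopifnot(length(vl_mean) == 6L, length(vl_sd) == 6L)
  if (any(vl_sd <= 0)) abort("all variation-level SDs must be positive")
  day_sb_pct <- setNames(as.numeric(day_sb_pct), DAY_TYPES)
  if (is.null(sb_target)) {
    dt <- rep(day_sb_pct / 100, each = 3L)
    sb_target <- setNames(dt * vl_mean / 100, FEATURE_COLS)
  } else {
    sb_target <- setNames(as.numeric(sb_target), FEATURE_COLS)
  }
  if (any(sb_target <= 0) || any(sb_target >= 1)) {
    abort("all period sedentary targets must lie strictly in (0, 1)")
  }
  sb_sd <- setNames(rep_len(as.numeric(sb_sd), 6L), FEATURE_COLS)
  if (any(sb_sd <= 0)) abort("sb_sd must be positive")
  if (mean_bout_sed < 1) abort("mean_bout_sed must be >= 1 minute")
  if (mvpa_share < 0 || mvpa_share > 1) abort("mvpa_share must be in [0, 1]")
  # Reference active-bout mean at the workday day-level target; the epoch
  # simulator rescales the active bout per period to hit each sb_target.
  sb_wd <- day_sb_pct[["workday"]] / 100
  structure(
    list(
      name = name, vl_mean = vl_mean, vl_sd = vl_sd,
      day_sb_pct = day_sb_pct, sb_target = sb_target, sb_sd = sb_sd,
      mean_bout_sed = mean_bout_sed,
      mean_bout_active = mean_bout_sed * (1 - sb_wd) / sb_wd,
      mvpa_share = mvpa_share
    ),
    class = "sed_archetype"
  )
}

#' @export
print.sed_archetype <- function(x, ...) {
  cat("<sed_archetype> ", x$name, "\n", sep = "")
  cat("  variation-level means:",
    paste(sprintf("%.1f", x$vl_mean), collapse = " "), "\n")
  cat("  day SB% (workday/non-workday):",
    sprintf("%.1f / %.1f", x$day_sb_pct[1], x$day_sb_pct[2]), "\n")
  invisible(x)
}

#' The four desk-worker typology archetypes
#'
#' Generative profiles of the four diurnal sedentary-behavior typologies
#' observed among desk-based workers: stable sedentary (low fluctuation all
#' day), off-morning break (dip on non-workday mornings), off-afternoon
#' break (dip on non-workday afternoons), and evening sedentary (evening
#' spike on both day types). For each cluster and day type the published
#' profile names the smallest and largest period mean; the third period mean
#' is completed through the equal-wear identity (the three period variation
#' levels of a day type average to 100 when wear time is balanced), and the
#' unnamed SD is interpolated as the mean of the two named SDs. Day-level
#' sedentary percentages, sedentary-break rates (hence mean sedentary bout
#' lengths), and MVPA shares come from the corresponding group summaries.
#'
#' @return Named list of four [archetype_profile()] objects, in cluster
#'   order: `stable_sedentary`, `off_morning_break`, `off_afternoon_break`,
#'   `evening_sedentary`.
#' @examples
#' names(study_archetypes())
#' @export
study_archetypes <- function() {
  list(
    stable_sedentary = archetype_profile(
      "stable_sedentary",
      vl_mean = c(101.0, 106.1, 92.9, 100.9, 97.4, 101.7),
      vl_sd = c(10.4, 8.0, 12.8, 12.5, 12.1, 12.9),
      day_sb_pct = c(65.1, 64.2),
      mean_bout_sed = 60 / 8.0, mvpa_share = 0.188
    ),
    off_morning_break = archetype_profile(
      "off_morning_break",
      vl_mean = c(93.5, 105.4, 101.1, 74.1, 104.4, 121.5),
      vl_sd = c(10.1, 10.0, 10.05, 11.1, 12.25, 13.4),
      day_sb_pct = c(62.4, 55.2),
      mean_bout_sed = 60 / 8.9, mvpa_share = 0.176
    ),
    off_afternoon_break = archetype_profile(
      "off_afternoon_break",
      vl_mean = c(91.4, 109.8, 98.8, 84.9, 66.1, 149.0),
      vl_sd = c(7.5, 7.7, 7.6, 20.6, 15.4, 25.8),
      day_sb_pct = c(64.0, 47.4),
      mean_bout_sed = 60 / 8.9, mvpa_share = 0.199
    ),
    evening_sedentary = archetype_profile(
      "evening_sedentary",
      vl_mean = c(83.2, 91.6, 125.2, 88.0, 87.7, 124.3),
      vl_sd = c(11.3, 13.2, 15.1, 13.25, 9.1, 17.4),
      day_sb_pct = c(55.8, 59.1),
      mean_bout_sed = 60 / 10.0, mvpa_share = 0.139
    )
  )
}

#' Observed mixing proportions of the four typologies
#'
#' @return Named numeric vector summing to 1 (cluster shares 46.7%, 26.6%,
#'   8.3%, 18.3%, renormalized).
#' @export
study_mixture_weights <- function() {
  w <- c(
    stable_sedentary = 0.467, off_morning_break = 0.266,
    off_afternoon_break = 0.083, evening_sedentary = 0.183
  )
  w / sum(w)
}
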