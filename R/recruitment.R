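#' Configure a recruitment fixture with engineered exclusions
#'
#' Describes a synthetic recruited cohort in which known, disjoint subsets
#' of participants fail each step of the analysis filter chain: insufficient
#' accelerometer wear, a missing work-domain self-reported sedentary-time
#' item, and missing sociodemographic covariates.
#'
#' @param n_total Recruited participants.
#' @param n_fail_wear Participants engineered to fail accelerometer
#'   eligibility (they contribute only 2 valid workdays and 1 non-workday).
#' @param n_missing_work_sb Participants missing the work-domain
#'   self-report item.
#' @param n_missing_covariates Participants with a missing sociodemographic
#'   covariate.
#' @param seed Integer seed (controls which participants fail).
#'
#' @return A `sed_recruitment_config` list.
#' @export
recruitment_config <- function(n_total, n_fail_wear, n_missing_work_sb,
                               n_missing_covariates, seed = 1L) {
  counts <- c(n_fail_wear, n_missing_work_sb, n_missing_covariates)
  if (any(counts < 0) || n_total < 0) abort("counts must be non-negative")
  if (sum(counts) > n_total) {
    abort("failure categories exceed n_total; they must be disjoint subsets")
  }
  structure(
    list(
      n_total = as.integer(n_total),
      n_fail_wear = as.integer(n_fail_wear),
      n_missing_work_sb = as.integer(n_missing_work_sb),
      n_missing_covariates = as.integer(n_missing_covariates),
      seed = as.integer(seed)
    ),
    class = "sed_recruitment_config"
  )
}

# One synthetic valid participant-day at the day-metrics level, long by
# scope. Built directly (not via epoch simulation) so large fixtures stay
# cheap; flagged validity is what the filter chain consumes.
synthetic_day_rows <- function(id, date, day_type, valid = TRUE,
                               period_valid = valid) {
  wear <- if (valid) c(whole_day = 900, morning = 300,
                       afternoon = 360, evening = 240)
          else c(whole_day = 480, morning = 40, afternoon = 360, evening = 80)
  sb <- round(wear * 0.6)
  lipa <- round(wear * 0.3)
  mvpa <- wear - sb - lipa
  tibble::tibble(
    participant_id = id, date = date, day_type = day_type,
    scope = names(wear),
    wear_min = unname(wear), sb_min = unname(sb),
    lipa_min = unname(lipa), mvpa_min = unname(mvpa),
    sb_pct = 100 * unname(sb) / unname(wear),
    lipa_pct = 100 * unname(lipa) / unname(wear),
    mvpa_pct = 100 * unname(mvpa) / unname(wear),
    breaks = round(unname(sb) / 8),
    breaks_per_sed_hour = round(unname(sb) / 8) / (unname(sb) / 60),
    valid_day = valid, period_valid = period_valid
  )
}

#' Generate a recruited cohort with engineered filter failures
#'
#' Builds a day-metrics table, a work-domain self-report table, and a
#' covariate table for `n_total` participants in which exactly the
#' configured numbers fail each filter: wear-failing participants have only
#' 2 valid workdays (plus 1 valid non-workday), self-report failures have
#' `work_sb_min = NA` on workdays, covariate failures have a missing
#' covariate value. All remaining participants pass every filter. The three
#' failure groups are disjoint by construction; which participants land in
#' each group is a seeded draw. The day-metrics rows are synthetic
#' (constructed at the metrics level, not via epoch simulation).
#'
#' @param config A [recruitment_config()].
#'
#' @return List with `day_metrics`, `work_sb`, `covariates`, and
#'   `assignment` (tibble: `participant_id`, `status`).
#' @examples
#' fx <- generate_recruitment_fixture(recruitment_config(10, 2, 1, 1))
#' exclusion_flow(fx)
#' @export
generate_recruitment_fixture <- function(config) {
  n <- config$n_total
  ids <- sprintf("R%04d", seq_len(n))
  status <- rep("pass", n)
  fail_idx <- with_local_seed(
    config$seed,
    sample.int(
      n,
      config$n_fail_wear + config$n_missing_work_sb +
        config$n_missing_covariates
    )
  )
  k1 <- config$n_fail_wear
  k2 <- config$n_missing_work_sb
  k3 <- config$n_missing_covariates
  status[fail_idx[seq_len(k1)]] <- "fail_wear"
  if (k2 > 0) status[fail_idx[k1 + seq_len(k2)]] <- "missing_work_sb"
  if (k3 > 0) status[fail_idx[k1 + k2 + seq_len(k3)]] <- "missing_covariates"

  base <- as.Date("2014-06-02") # Monday
  day_plan_full <- tibble::tibble(
    date = base + 0:6,
    day_type = rep(c("workday", "non_workday"), c(5L, 2L)),
    valid = TRUE
  )
  # Wear failures: only 2 valid workdays (days 3-5 invalid), 1 non-workday.
  day_plan_fail <- day_plan_full
  day_plan_fail$valid <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)

  dm <- purrr::map2_dfr(ids, status, function(id, st) {
    plan <- if (st == "fail_wear") day_plan_fail else day_plan_full
    purrr::pmap_dfr(plan, function(date, day_type, valid) {
      synthetic_day_rows(id, date, day_type, valid = valid)
    })
  })
  work_sb <- tibble::tibble(
    participant_id = ids,
    work_sb_min = ifelse(status == "missing_work_sb", NA_real_, 420)
  )
  covariates <- tibble::tibble(
    participant_id = ids,
    sex = ifelse(status == "missing_covariates", NA_character_,
      rep_len(c("women", "men"), n)
    ),
    age = 50
  )
  list(
    day_metrics = dm,
    work_sb = work_sb,
    covariates = covariates,
    assignment = tibble::tibble(participant_id = ids, status = status)
  )
}

#' Apply the analysis filter chain and count exclusions
#'
#' Runs the eligibility and missing-data filters in order — accelerometer
#' eligibility first, then presence of the work-domain self-report, then
#' complete covariates — and reports the telescoping counts.
#'
#' @param fixture Output of [generate_recruitment_fixture()], or any list
#'   with `day_metrics`, `work_sb`, `covariates` in the same shapes.
#'
#' @return List with `counts` (tibble: `stage`, `n_excluded`, `n_remaining`)
#'   and `analyzed` (character vector of retained participant ids).
#' @export
exclusion_flow <- function(fixture) {
  elig <- assess_eligibility(fixture$day_metrics)
  ids0 <- unique(fixture$day_metrics$participant_id)
  keep1 <- elig$participant_id[elig$eligible]
  n_wear <- length(ids0) - length(keep1)

  ws <- fixture$work_sb
  keep2 <- intersect(keep1, ws$participant_id[!is.na(ws$work_sb_min)])
  n_ws <- length(keep1) - length(keep2)

  cov <- fixture$covariates
  cov_complete <- cov$participant_id[complete.cases(
    dplyr::select(cov, -"participant_id")
  )]
  keep3 <- intersect(keep2, cov_complete)
  n_cov <- length(keep2) - length(keep3)

  counts <- tibble::tibble(
    stage = c(
      "recruited", "insufficient_accelerometer_data",
      "missing_work_domain_self_report", "missing_covariates", "analyzed"
    ),
    n_excluded = c(NA_integer_, n_wear, n_ws, n_cov, NA_integer_),
    n_remaining = c(
      length(ids0), length(keep1), length(keep2), length(keep3),
      length(keep3)
    )
  )
  list(counts = counts, analyzed = keep3)
}
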