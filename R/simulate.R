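#' Configure a synthetic cohort
#'
#' Holds the design of a simulated cohort: size, archetype mixture, the
#' measurement week (workdays and non-workdays per participant), wake-window
#' variability, and device-off gap behavior. Defaults describe a typical
#' working adult measured over one week: five workdays and a two-day
#' non-work weekend, waking around 07:00 and retiring around 23:00 (SD 30
#' minutes, clipped to the 06:00-24:00 analysis window), with on average one
#' mid-day device-off gap of 75 minutes per day.
#'
#' @param n_participants Number of participants.
#' @param mixture_weights Per-archetype mixing probabilities; must sum to 1.
#' @param n_workdays,n_nonworkdays Measured days per participant. An
#'   eligible-by-construction cohort needs at least 3 workdays and 1
#'   non-workday.
#' @param wake_start_mean,wake_start_sd Wake-window start: mean clock time
#'   ("HH:MM" or minutes from midnight) and SD in minutes.
#' @param wake_end_mean,wake_end_sd Wake-window end, likewise.
#' @param nonwear_gap_rate Expected number of mid-day device-off gaps per
#'   day (Poisson).
#' @param nonwear_gap_length Gap length, minutes.
#' @param start_date First measured date (a Monday keeps the default
#'   week layout of 5 workdays then a weekend).
#' @param seed Integer seed; every simulator draw flows from it.
#'
#' @return A `sed_cohort_config` list.
#' @export
cohort_config <- function(n_participants,
                          mixture_weights = study_mixture_weights(),
                          n_workdays = 5L, n_nonworkdays = 2L,
                          wake_start_mean = "07:00", wake_start_sd = 30,
                          wake_end_mean = "23:00", wake_end_sd = 30,
                          nonwear_gap_rate = 1, nonwear_gap_length = 75,
                          start_date = as.Date("2014-06-02"),
                          seed = 1L) {
  if (abs(sum(mixture_weights) - 1) > 1e-9) {
    abort("mixture_weights must sum to 1")
  }
  if (any(mixture_weights < 0)) abort("mixture_weights must be non-negative")
  ws <- clock_minutes(wake_start_mean)
  we <- clock_minutes(wake_end_mean)
  if (we - ws < 60) abort("wake window must be at least 60 minutes")
  structure(
    list(
      n_participants = as.integer(n_participants),
      mixture_weights = mixture_weights,
      n_workdays = as.integer(n_workdays),
      n_nonworkdays = as.integer(n_nonworkdays),
      wake_start_mean = ws, wake_start_sd = wake_start_sd,
      wake_end_mean = we, wake_end_sd = wake_end_sd,
      nonwear_gap_rate = nonwear_gap_rate,
      nonwear_gap_length = as.integer(nonwear_gap_length),
      start_date = as.Date(start_date),
      seed = as.integer(seed)
    ),
    class = "sed_cohort_config"
  )
}

draw_labels <- function(config, n_arch) {
  vapply(seq_len(config$n_participants), function(i) {
    with_local_seed(
      participant_seed(config$seed, i, salt = 1L),
      sample.int(n_arch, 1L, prob = config$mixture_weights)
    )
  }, integer(1))
}

check_archetypes <- function(config, archetypes) {
  if (length(archetypes) < 1L) abort("need at least one archetype")
  if (length(config$mixture_weights) != length(archetypes)) {
    abort("mixture_weights and archetypes must have equal length")
  }
  if (config$n_participants < length(archetypes)) {
    warn("fewer participants than archetypes; some may go unrepresented")
  }
  invisible(TRUE)
}

#' Simulate a feature-level cohort with known cluster structure
#'
#' Draws each participant's archetype label from the mixture weights, then
#' draws the six variation-level features independently per dimension from a
#' normal distribution with that archetype's mean and SD. Each participant
#' has a private RNG stream keyed by `(seed, index)`, so enlarging the
#' cohort never changes already-generated participants.
#'
#' @param config A [cohort_config()].
#' @param archetypes List of [archetype_profile()] objects, one per mixture
#'   component.
#'
#' @return A list with `features` (tibble: `participant_id` plus the six
#'   feature columns) and `labels` (tibble: `participant_id`, `archetype`).
#' @examples
#' cohort <- generate_feature_cohort(
#'   cohort_config(20, seed = 1),
#'   study_archetypes()
#' )
#' head(cohort$features)
#' @export
generate_feature_cohort <- function(config, archetypes) {
  check_archetypes(config, archetypes)
  n <- config$n_participants
  labels <- draw_labels(config, length(archetypes))
  ids <- sprintf("P%04d", seq_len(n))
  feats <- matrix(NA_real_, n, 6L, dimnames = list(NULL, FEATURE_COLS))
  for (i in seq_len(n)) {
    a <- archetypes[[labels[i]]]
    feats[i, ] <- with_local_seed(
      participant_seed(config$seed, i, salt = 2L),
      rnorm(6L, a$vl_mean, a$vl_sd)
    )
  }
  arch_names <- vapply(archetypes, `[[`, character(1), "name")
  list(
    features = dplyr::bind_cols(
      tibble::tibble(participant_id = ids),
      tibble::as_tibble(feats)
    ),
    labels = tibble::tibble(
      participant_id = ids, archetype = arch_names[labels]
    )
  )
}

# Simulate one wear day as alternating sedentary/active bouts with geometric
# (memoryless) lengths. The sedentary bout mean is the archetype's; the
# active bout mean is rescaled per period so the stationary sedentary
# fraction equals the participant's period propensity. At period boundaries
# the current state is kept and the residual bout redrawn under the new
# period's parameter, which is distributionally exact for memoryless bouts.
simulate_day_mets <- function(prop, wake_start, wake_end, l_sed,
                              mvpa_share, gap_rate, gap_len) {
  mets <- runif(1440L, 0.1, 0.85) # device off / asleep
  boundaries <- c(720L, 1080L, 1440L)
  t <- wake_start
  p_now <- function(t) period_of_minute(t)
  state <- runif(1) < prop[[p_now(t)]] # TRUE = sedentary, stationary start
  states <- logical(0)
  while (t < wake_end) {
    period <- p_now(t)
    sb <- prop[[period]]
    # bouts are whole minutes (>= 1), so extreme sedentary fractions need a
    # longer sedentary bout rather than a sub-minute active bout
    l_sed_eff <- max(l_sed, sb / (1 - sb))
    len_mean <- if (state) l_sed_eff else l_sed_eff * (1 - sb) / sb
    len <- 1L + rgeom(1L, 1 / max(len_mean, 1))
    boundary <- min(c(boundaries[boundaries > t], wake_end))
    cut <- min(t + len, boundary, wake_end)
    run <- cut - t
    states <- c(states, rep(state, run))
    t <- cut
    if (t < wake_end && t == boundary) next # redraw same state, new period
    state <- !state
  }
  idx <- wake_start + seq_along(states)
  sed <- states
  mets[idx[sed]] <- runif(sum(sed), 1.05, 1.5)
  n_act <- sum(!sed)
  if (n_act > 0) {
    is_mvpa <- runif(n_act) < mvpa_share
    act_mets <- ifelse(is_mvpa, runif(n_act, 3.0, 6.0), runif(n_act, 1.6, 2.95))
    mets[idx[!sed]] <- act_mets
  }
  # Mid-day device-off gaps, discoverable by the non-wear detector.
  n_gaps <- rpois(1L, gap_rate)
  if (n_gaps > 0 && wake_end - wake_start > gap_len) {
    for (g in seq_len(n_gaps)) {
      g0 <- floor(runif(1, wake_start, wake_end - gap_len))
      mets[(g0 + 1):(g0 + gap_len)] <- runif(gap_len, 0.1, 0.85)
    }
  }
  mets
}

#' Simulate an epoch-level cohort (minute METs series plus diary)
#'
#' Produces, per participant-day, a full 1440-minute METs vector. Minutes
#' outside the participant's simulated wake window, and injected device-off
#' gaps, emit METs <= 0.9; within wear, sedentary and active bouts alternate
#' as a two-state chain with memoryless bout lengths whose stationary
#' sedentary fraction matches the participant's period-specific propensity
#' (drawn once per participant around the archetype's `sb_target`, truncated
#' to (0.02, 0.98)). Active minutes are MVPA (>= 3.0 METs) with the
#' archetype's `mvpa_share`, otherwise light activity. Wake windows are
#' normal draws clipped to `[06:00, 24:00)`.
#'
#' @inheritParams generate_feature_cohort
#'
#' @return A list with `epochs` (tibble: `participant_id`, `timestamp`
#'   (POSIXct UTC, minute resolution), `mets`), `diary` (tibble:
#'   `participant_id`, `date`, `day_type`), and `labels`.
#' @examples
#' sim <- generate_epoch_cohort(
#'   cohort_config(2, n_workdays = 3, n_nonworkdays = 1, seed = 1),
#'   study_archetypes()
#' )
#' dplyr::count(sim$diary, day_type)
#' @export
generate_epoch_cohort <- function(config, archetypes) {
  check_archetypes(config, archetypes)
  for (a in archetypes) {
    if (any(a$sb_target <= 0) || any(a$sb_target >= 1)) {
      abort("degenerate bout chain: sb_target must be strictly inside (0, 1)")
    }
  }
  if (config$wake_end_mean - config$wake_start_mean < 60) {
    abort("wake window must be at least 60 minutes")
  }
  n <- config$n_participants
  labels <- draw_labels(config, length(archetypes))
  ids <- sprintf("P%04d", seq_len(n))
  # Week layout: Mon-Fri workdays, Sat-Sun non-workdays, repeating.
  day_types <- rep(
    rep(c("workday", "non_workday"), times = c(5L, 2L)),
    length.out = 7L * ceiling(max(config$n_workdays / 5, config$n_nonworkdays / 2))
  )
  wd_dates <- config$start_date + which(day_types == "workday") - 1L
  nw_dates <- config$start_date + which(day_types == "non_workday") - 1L
  dates <- sort(c(
    head(wd_dates, config$n_workdays),
    head(nw_dates, config$n_nonworkdays)
  ))
  dtype <- ifelse(
    dates %in% head(wd_dates, config$n_workdays), "workday", "non_workday"
  )
  n_days <- length(dates)

  epoch_list <- vector("list", n)
  for (i in seq_len(n)) {
    a <- archetypes[[labels[i]]]
    mets_all <- with_local_seed(participant_seed(config$seed, i, salt = 3L), {
      # participant-level period propensities per day type
      prop <- pmin(pmax(rnorm(6L, a$sb_target, a$sb_sd), 0.02), 0.98)
      names(prop) <- FEATURE_COLS
      unlist(lapply(seq_len(n_days), function(d) {
        dt_prefix <- if (dtype[d] == "workday") "workday" else "non_workday"
        p_day <- setNames(
          prop[paste0(dt_prefix, "_", PERIODS)],
          PERIODS
        )
        ws <- round(rnorm(1, config$wake_start_mean, config$wake_start_sd))
        we <- round(rnorm(1, config$wake_end_mean, config$wake_end_sd))
        ws <- min(max(ws, MINUTES_DAY_START), MINUTES_DAY_END - 61L)
        we <- min(max(we, ws + 60L), MINUTES_DAY_END)
        simulate_day_mets(
          p_day, ws, we, a$mean_bout_sed, a$mvpa_share,
          config$nonwear_gap_rate, config$nonwear_gap_length
        )
      }))
    })
    # days need not be consecutive; build per-day minute stamps
    stamps <- as.POSIXct(
      rep(paste(dates, "00:00:00"), each = 1440L),
      tz = "UTC"
    ) + rep(0:1439 * 60, times = n_days)
    epoch_list[[i]] <- tibble::tibble(
      participant_id = ids[i],
      timestamp = stamps,
      mets = round(mets_all, 3)
    )
  }
  arch_names <- vapply(archetypes, `[[`, character(1), "name")
  list(
    epochs = dplyr::bind_rows(epoch_list),
    diary = tidyr::crossing(
      participant_id = ids,
      tibble::tibble(date = dates, day_type = dtype)
    ),
    labels = tibble::tibble(
      participant_id = ids, archetype = arch_names[labels]
    )
  )
}

#' Simulate cluster-linked categorical sociodemographics
#'
#' Draws one categorical covariate row per participant from
#' cluster-conditional category distributions, emulating the structure of a
#' characteristics-by-cluster table.
#'
#' @param labels Tibble with `participant_id` and `archetype` (or any
#'   cluster label column named by `label_col`).
#' @param category_specs Named list, one element per covariate. Each element
#'   is a named list mapping cluster label to a named probability vector
#'   over categories (probabilities must sum to 1 per cluster).
#' @param seed Integer seed.
#' @param label_col Name of the cluster label column in `labels`.
#'
#' @return Tibble: `participant_id` plus one character column per covariate.
#' @examples
#' labs <- tibble::tibble(
#'   participant_id = c("a", "b"),
#'   archetype = c("x", "y")
#' )
#' spec <- list(sex = list(
#'   x = c(women = 0.5, men = 0.5),
#'   y = c(women = 0.7, men = 0.3)
#' ))
#' generate_sociodemographic_table(labs, spec, seed = 1)
#' @export
generate_sociodemographic_table <- function(labels, category_specs, seed,
                                            label_col = "archetype") {
  for (var in names(category_specs)) {
    for (cl in names(category_specs[[var]])) {
      p <- category_specs[[var]][[cl]]
      if (abs(sum(p) - 1) > 1e-9) {
        abort(paste0(
          "probabilities for '", var, "' in cluster '", cl,
          "' do not sum to 1"
        ))
      }
    }
  }
  n <- nrow(labels)
  out <- tibble::tibble(participant_id = labels$participant_id)
  cl <- labels[[label_col]]
  for (v in seq_along(category_specs)) {
    var <- names(category_specs)[v]
    spec <- category_specs[[var]]
    missing_cl <- setdiff(unique(cl), names(spec))
    if (length(missing_cl) > 0) {
      abort(paste0(
        "no category probabilities for cluster(s): ",
        paste(missing_cl, collapse = ", ")
      ))
    }
    col <- vapply(seq_len(n), function(i) {
      p <- spec[[cl[i]]]
      with_local_seed(
        participant_seed(seed, i, salt = 100L + v),
        sample(names(p), 1L, prob = p)
      )
    }, character(1))
    out[[var]] <- col
  }
  out
}
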