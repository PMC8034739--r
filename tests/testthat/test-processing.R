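test_that("intensity cut-points sit exactly on the boundaries", {
  expect_equal(
    classify_intensity(c(1.0, 1.5, 1.51, 2.99, 3.0, 6.0)),
    c("SB", "SB", "LIPA", "LIPA", "MVPA", "MVPA")
  )
  expect_error(classify_intensity(-0.1), "non-negative")
})

test_that("non-wear rule: 60-minute threshold and two-minute allowance", {
  mask_of <- function(mets) detect_nonwear(make_epochs(mets))$nonwear
  # 70 low epochs: all non-wear
  expect_true(all(mask_of(rep(0.9, 70))))
  # 59 low epochs flanked by activity: all wear
  expect_true(!any(mask_of(c(2, rep(0.9, 59), 2))))
  # two tolerated interruptions are absorbed into one 62-epoch interval
  m <- mask_of(c(rep(0.9, 30), rep(1.0, 2), rep(0.9, 30)))
  expect_equal(sum(m), 62)
  # three interruptions break the window
  expect_true(!any(mask_of(c(rep(0.9, 30), rep(1.0, 3), rep(0.9, 30)))))
  # anything above 1.0 terminates regardless of run length
  expect_true(!any(mask_of(c(rep(0.9, 59), 1.01, rep(0.9, 59)))))
})

test_that("non-wear detection matches exhaustive window enumeration", {
  set.seed(42)
  for (case in 1:200) {
    n <- sample(60:500, 1)
    mets <- random_mets_series(n)
    got <- detect_nonwear(make_epochs(mets))$nonwear
    expect_identical(got, oracle_nonwear(mets))
  }
})

test_that("lowering an epoch's METs never decreases non-wear time", {
  set.seed(7)
  for (case in 1:50) {
    mets <- random_mets_series(200)
    base <- sum(detect_nonwear(make_epochs(mets))$nonwear)
    i <- sample(200, 1)
    mets[i] <- 0.5
    expect_gte(sum(detect_nonwear(make_epochs(mets))$nonwear), base)
  }
})

test_that("non-wear detection spans midnight on contiguous series", {
  # 23:20-00:30: a 70-minute off block split 40/30 across the day boundary
  mets <- c(rep(2, 10), rep(0.5, 70), rep(2, 10))
  ep <- make_epochs(mets, start = "2014-06-02 23:10")
  expect_equal(sum(detect_nonwear(ep)$nonwear), 70)
})

test_that("sedentary breaks count wear SB-to-non-SB transitions only", {
  expect_equal(count_breaks(c("SB", "SB", "LIPA", "SB", "MVPA")), 2)
  expect_equal(count_breaks(rep("SB", 5)), 0)
  # a non-wear boundary is not a break
  intensity <- c("SB", "SB", "SB", "SB", "SB")
  nonwear <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(count_breaks(intensity, nonwear), 0)
  # scope restriction: only transitions whose non-SB epoch is in scope
  intensity <- c("SB", "LIPA", "SB", "LIPA")
  expect_equal(
    count_breaks(intensity, in_scope = c(FALSE, FALSE, TRUE, TRUE)), 1
  )
})

test_that("breaks never exceed the number of maximal sedentary runs", {
  set.seed(11)
  for (case in 1:50) {
    intensity <- sample(c("SB", "LIPA", "MVPA"), 120, replace = TRUE)
    nonwear <- runif(120) < 0.2
    wear_int <- ifelse(nonwear, "X", intensity)
    runs <- rle(wear_int)
    n_sb_runs <- sum(runs$values == "SB")
    expect_lte(count_breaks(intensity, nonwear), n_sb_runs)
  }
})

test_that("day summaries respect validity boundaries and conservation", {
  day_of <- function(wear_epochs) {
    # wear_epochs minutes of 1.2 METs starting 06:00, off before/after
    mets <- c(rep(0.5, 360), rep(1.2, wear_epochs), rep(0.5, 1080 - wear_epochs))
    ep <- detect_nonwear(make_epochs(mets, start = "2014-06-02 00:00"))
    summarize_day(ep, day_type = "workday")
  }
  d600 <- day_of(600)
  expect_true(all(d600$valid_day))
  d599 <- day_of(599)
  expect_false(any(d599$valid_day))
  # constant 1.2 METs full window: all sedentary, no breaks
  full <- day_of(1080)
  expect_true(all(full$period_valid))
  wd <- full[full$scope == "whole_day", ]
  expect_equal(wd$sb_pct, 100)
  expect_equal(wd$breaks, 0L)
  # conservation: intensities partition wear, periods partition the day
  expect_equal(full$sb_min + full$lipa_min + full$mvpa_min, full$wear_min)
  expect_equal(
    sum(full$wear_min[full$scope != "whole_day"]), wd$wear_min
  )
})

test_that("90 wear minutes per period meet the period-validity boundary", {
  # 90 min of wear at the start of each period, otherwise off
  block <- function() c(rep(1.2, 90), rep(0.5, 270))
  mets <- c(rep(0.5, 360), block(), block(), block())
  ep <- detect_nonwear(make_epochs(mets, start = "2014-06-02 00:00"))
  d <- summarize_day(ep, "workday")
  expect_true(all(d$wear_min[d$scope != "whole_day"] == 90))
  expect_false(any(d$valid_day)) # 270 wear min < 600
  mets2 <- c(rep(0.5, 360), rep(1.2, 1080))
  d2 <- summarize_day(
    detect_nonwear(make_epochs(mets2, start = "2014-06-02 00:00")), "workday"
  )
  expect_true(all(d2$period_valid))
})

test_that("scopes without wear are flagged NA rather than zero", {
  mets <- c(rep(0.5, 360), rep(1.2, 360), rep(0.5, 720))
  d <- summarize_day(
    detect_nonwear(make_epochs(mets, start = "2014-06-02 00:00")), "workday"
  )
  expect_true(is.na(d$sb_pct[d$scope == "evening"]))
  expect_true(is.na(d$breaks_per_sed_hour[d$scope == "evening"]))
})

test_that("eligibility requires the full day-type pattern", {
  mk_days <- function(valid_wd, valid_nw, invalid_wd = 0) {
    rows <- list()
    d <- as.Date("2014-06-02")
    add <- function(day_type, valid) {
      r <- synthetic_day_rows_for_test(d, day_type, valid)
      d <<- d + 1
      r
    }
    dplyr::bind_rows(
      lapply(seq_len(valid_wd), function(i) add("workday", TRUE)),
      lapply(seq_len(invalid_wd), function(i) add("workday", FALSE)),
      lapply(seq_len(valid_nw), function(i) add("non_workday", TRUE))
    )
  }
  synthetic_day_rows_for_test <- function(date, day_type, valid) {
    tibble::tibble(
      participant_id = "p", date = date, day_type = day_type,
      scope = c("whole_day", "morning", "afternoon", "evening"),
      wear_min = if (valid) c(900, 300, 300, 300) else c(300, 100, 100, 100),
      sb_min = 0, lipa_min = 0, mvpa_min = 0, sb_pct = 0, lipa_pct = 0,
      mvpa_pct = 0, breaks = 0L, breaks_per_sed_hour = NA_real_,
      valid_day = valid, period_valid = valid
    )
  }
  expect_true(assess_eligibility(mk_days(3, 1))$eligible)
  e <- assess_eligibility(mk_days(4, 0))
  expect_false(e$eligible)
  expect_match(e$reasons, "no valid non-workday")
  e0 <- assess_eligibility(mk_days(0, 0, invalid_wd = 2))
  expect_false(e0$eligible)
  expect_match(e0$reasons, "fewer than 4 valid days")
  expect_match(e0$reasons, "fewer than 3 valid workdays")
  expect_match(e0$reasons, "no period-valid non-workday")
})

test_that("a day missing from the diary is reported by name", {
  sim <- generate_epoch_cohort(
    cohort_config(1,
      mixture_weights = 1, n_workdays = 3, n_nonworkdays = 1, seed = 1
    ),
    study_archetypes()[1]
  )
  diary <- sim$diary[-2, ]
  expect_error(
    compute_day_metrics(sim$epochs, diary),
    "no diary entry for participant P0001"
  )
})
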