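test_that("degenerate single-archetype mixture collapses to the mean vector", {
  a <- archetype_profile(
    "flat", vl_mean = rep(100, 6), vl_sd = rep(1e-9, 6),
    day_sb_pct = c(60, 60)
  )
  cohort <- generate_feature_cohort(
    cohort_config(5, mixture_weights = 1, seed = 3), list(a)
  )
  m <- feature_matrix(cohort$features)
  expect_equal(unname(m), matrix(100, 5, 6), tolerance = 1e-6)
  expect_true(all(cohort$labels$archetype == "flat"))
})

test_that("feature cohorts are deterministic and stable under cohort growth", {
  arch <- study_archetypes()
  c1 <- generate_feature_cohort(cohort_config(15, seed = 7), arch)
  c2 <- generate_feature_cohort(cohort_config(15, seed = 7), arch)
  expect_identical(c1, c2)
  c3 <- generate_feature_cohort(cohort_config(25, seed = 7), arch)
  expect_identical(c1$features, c3$features[1:15, ])
  expect_identical(c1$labels, c3$labels[1:15, ])
  c4 <- generate_feature_cohort(cohort_config(15, seed = 8), arch)
  expect_false(identical(c1$features, c4$features))
})

test_that("cohort configuration is validated", {
  expect_error(
    cohort_config(10, mixture_weights = c(0.5, 0.4)),
    "sum to 1"
  )
  expect_error(
    cohort_config(25,
      mixture_weights = 1,
      wake_start_mean = "22:00", wake_end_mean = "22:30"
    ),
    "60 minutes"
  )
  expect_warning(
    generate_feature_cohort(cohort_config(2, seed = 1), study_archetypes()),
    "fewer participants"
  )
})

test_that("near-saturated sedentary targets drive SB% toward 100 everywhere", {
  a <- archetype_profile(
    "sat", vl_mean = rep(100, 6), vl_sd = rep(1e-6, 6),
    day_sb_pct = c(99.9, 99.9), sb_sd = 1e-6, mvpa_share = 0
  )
  sim <- generate_epoch_cohort(
    cohort_config(3,
      mixture_weights = 1, n_workdays = 3, n_nonworkdays = 1,
      nonwear_gap_rate = 0, seed = 5
    ),
    list(a)
  )
  dm <- compute_day_metrics(sim$epochs, sim$diary)
  expect_true(all(dm$sb_pct[dm$wear_min > 0] > 95))
})

test_that("without gaps and a full wake window, wear is 1080 min/day", {
  a <- study_archetypes()$stable_sedentary
  sim <- generate_epoch_cohort(
    cohort_config(2,
      mixture_weights = 1, n_workdays = 3, n_nonworkdays = 1,
      wake_start_mean = "06:00", wake_start_sd = 0,
      wake_end_mean = "24:00", wake_end_sd = 0,
      nonwear_gap_rate = 0, seed = 2
    ),
    list(a)
  )
  dm <- compute_day_metrics(sim$epochs, sim$diary)
  expect_true(all(dm$wear_min[dm$scope == "whole_day"] == 1080))
})

test_that("stationary sedentary fractions track the archetype targets", {
  a <- study_archetypes()$evening_sedentary
  a$sb_sd[] <- 1e-4 # isolate the bout chain from between-person spread
  sim <- generate_epoch_cohort(
    cohort_config(25,
      mixture_weights = 1, n_workdays = 5, n_nonworkdays = 2,
      nonwear_gap_rate = 0, seed = 9
    ),
    list(a)
  )
  dm <- compute_day_metrics(sim$epochs, sim$diary)
  for (dt in c("workday", "non_workday")) {
    for (p in c("morning", "afternoon", "evening")) {
      frac <- dm$sb_pct[
        dm$day_type == dt & dm$scope == p & dm$wear_min > 0
      ] / 100
      target <- a$sb_target[[paste0(dt, "_", p)]]
      se <- sd(frac) / sqrt(length(frac))
      expect_gte(length(frac), 50)
      expect_lt(abs(mean(frac) - target), 3 * se + 0.01)
    }
  }
})

test_that("epoch cohorts are deterministic and diary-complete", {
  arch <- study_archetypes()[c(1, 4)]
  cfg <- cohort_config(
    3, mixture_weights = c(0.5, 0.5),
    n_workdays = 3, n_nonworkdays = 1, seed = 4
  )
  s1 <- generate_epoch_cohort(cfg, arch)
  s2 <- generate_epoch_cohort(cfg, arch)
  expect_identical(s1, s2)
  # every generated (participant, date) appears exactly once in the diary
  dates <- dplyr::distinct(
    dplyr::mutate(s1$epochs, date = as.Date(timestamp, tz = "UTC")),
    participant_id, date
  )
  joined <- dplyr::count(
    dplyr::inner_join(dates, s1$diary, by = c("participant_id", "date")),
    participant_id, date
  )
  expect_equal(nrow(joined), nrow(dates))
  expect_true(all(joined$n == 1))
  # off minutes are discoverable: everything outside wear emits <= 0.9
  expect_true(all(s1$epochs$mets >= 0))
})

test_that("sociodemographic draws follow cluster-conditional probabilities", {
  labs <- tibble::tibble(
    participant_id = sprintf("P%05d", 1:10000),
    archetype = rep(c("c1", "c2"), each = 5000)
  )
  spec <- list(sex = list(
    c1 = c(women = 0.439, men = 0.561),
    c2 = c(women = 0.690, men = 0.310)
  ))
  tab <- generate_sociodemographic_table(labs, spec, seed = 21)
  p1 <- mean(tab$sex[1:5000] == "women")
  p2 <- mean(tab$sex[5001:10000] == "women")
  expect_lt(abs(p1 - 0.439), 0.02)
  expect_lt(abs(p2 - 0.690), 0.02)
  # degenerate probabilities give a constant column
  const <- generate_sociodemographic_table(
    labs[1:50, ], list(v = list(c1 = c(x = 1))), seed = 1
  )
  expect_true(all(const$v == "x"))
  expect_error(
    generate_sociodemographic_table(
      labs[1:5, ], list(v = list(c1 = c(x = 0.5, y = 0.4))), seed = 1
    ),
    "sum to 1"
  )
})

test_that("identical cluster probabilities yield a calibrated null", {
  labs <- tibble::tibble(
    participant_id = sprintf("P%04d", 1:120),
    archetype = rep(c("c1", "c2", "c3", "c4"), each = 30)
  )
  spec <- list(v = lapply(
    setNames(nm = paste0("c", 1:4)),
    function(cl) c(a = 0.5, b = 0.5)
  ))
  reject <- vapply(1:100, function(s) {
    tab <- generate_sociodemographic_table(labs, spec, seed = 5000 + s)
    chi_square_test(table(tab$v, labs$archetype))$p < 0.05
  }, logical(1))
  expect_gte(mean(!reject), 0.9)
})

test_that("recruitment fixtures engineer exact filter counts", {
  fx <- generate_recruitment_fixture(recruitment_config(10, 2, 1, 1, seed = 2))
  flow <- exclusion_flow(fx)
  expect_equal(dplyr::last(flow$counts$n_remaining), 6)
  expect_equal(flow$counts$n_excluded[2:4], c(2L, 1L, 1L))

  fx0 <- generate_recruitment_fixture(recruitment_config(5, 0, 0, 0))
  expect_equal(length(exclusion_flow(fx0)$analyzed), 5)

  expect_error(recruitment_config(10, 8, 2, 1), "exceed")
})

test_that("exclusion-flow counts telescope", {
  fx <- generate_recruitment_fixture(recruitment_config(40, 7, 4, 3, seed = 6))
  cnt <- exclusion_flow(fx)$counts
  expect_equal(
    cnt$n_remaining[1] - sum(cnt$n_excluded, na.rm = TRUE),
    dplyr::last(cnt$n_remaining)
  )
  # wear-failing participants are genuinely ineligible under the rules
  elig <- assess_eligibility(fx$day_metrics)
  merged <- dplyr::inner_join(elig, fx$assignment, by = "participant_id")
  expect_true(all(!merged$eligible[merged$status == "fail_wear"]))
  expect_true(all(merged$eligible[merged$status != "fail_wear"]))
  expect_match(
    merged$reasons[merged$status == "fail_wear"][1],
    "fewer than 3 valid workdays"
  )
})
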