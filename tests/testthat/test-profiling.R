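test_that("one-way ANOVA handles the degenerate and separated limits", {
  expect_equal(
    anova_oneway(rep(5, 8), rep(c("a", "b"), each = 4))$F, 0
  )
  sep <- anova_oneway(
    c(0, 0, 0, 1, 1, 1) + rnorm(6, sd = 1e-6),
    rep(c("a", "b"), each = 3)
  )
  expect_lt(sep$p, 1e-6)
  expect_error(
    anova_oneway(c(1, 2, 3), c("a", "a", "b")),
    "'b' has fewer than 2"
  )
})

test_that("summary-statistic ANOVA is an exact round trip of raw ANOVA", {
  set.seed(53)
  for (case in 1:20) {
    k <- sample(2:5, 1)
    ns <- sample(5:20, k, replace = TRUE)
    g <- rep(letters[1:k], ns)
    y <- rnorm(sum(ns), mean = rep(rnorm(k, sd = 2), ns))
    raw <- anova_oneway(y, g)
    summ <- anova_from_summary(
      tapply(y, g, mean), tapply(y, g, sd), ns,
      labels = letters[1:k]
    )
    expect_equal(summ$F, raw$F, tolerance = 1e-9)
    expect_equal(summ$p, raw$p, tolerance = 1e-9)
    expect_equal(summ$pairwise$p_adj, raw$pairwise$p_adj, tolerance = 1e-9)
  }
  expect_error(anova_from_summary(c(1, 2), c(1, 0), c(5, 5)), "positive")
})

test_that("two-group summary ANOVA equals the pooled t test", {
  f <- anova_from_summary(c(10, 12), c(3, 3.5), c(20, 25))
  # algebraic identity F = t^2 with pooled variance
  sp2 <- (19 * 9 + 24 * 3.5^2) / 43
  tstat <- (10 - 12) / sqrt(sp2 * (1 / 20 + 1 / 25))
  expect_equal(f$F, tstat^2, tolerance = 1e-12)
})

test_that("Bonferroni pairwise tests match the pooled reference", {
  set.seed(59)
  y <- rnorm(60, mean = rep(c(0, 0.5, 1), each = 20))
  g <- rep(c("a", "b", "c"), each = 20)
  res <- anova_oneway(y, g)
  ref <- stats::pairwise.t.test(
    y, g, p.adjust.method = "bonferroni", pool.sd = TRUE
  )
  expect_equal(res$pairwise$p_adj[1], ref$p.value["b", "a"], tolerance = 1e-9)
  expect_equal(res$pairwise$p_adj[2], ref$p.value["c", "a"], tolerance = 1e-9)
  expect_equal(res$pairwise$p_adj[3], ref$p.value["c", "b"], tolerance = 1e-9)
  # adjusted p always within [raw p, 1]
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adj <= 1))
})

test_that("chi-square results reproduce the printed cluster tables", {
  tabs <- table1_counts()
  expect_equal(round(chi_square_test(tabs$sex)$p, 3), 0.019)
  expect_equal(round(chi_square_test(tabs$income)$p, 3), 0.016)
  expect_equal(round(chi_square_test(tabs$sleep)$p, 3), 0.002)
  expect_equal(round(chi_square_test(tabs$marital)$p, 3), 0.894)
})

test_that("adjusted residuals follow the closed form and flag rule", {
  tab <- table1_counts()$sex
  res <- chi_square_test(tab)
  # hand formula on one cell
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  r_hand <- (tab[1, 4] - e[1, 4]) /
    sqrt(e[1, 4] * (1 - rowSums(tab)[1] / n) * (1 - colSums(tab)[4] / n))
  expect_equal(res$adjusted_residuals[1, 4], unname(r_hand), tolerance = 1e-9)
  expect_equal(round(res$adjusted_residuals[1, 4], 2), 3.08)
  expect_true(res$flags[1, 4])
  # residual zero-sums over every row and column
  delta <- res$observed - res$expected
  expect_true(all(abs(rowSums(delta)) < 1e-9))
  expect_true(all(abs(colSums(delta)) < 1e-9))
})

test_that("an exactly independent table gives chi2 = 0 and no flags", {
  tab <- outer(c(20, 30), c(10, 40, 50)) / 100
  res <- chi_square_test(tab)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_false(any(res$flags))
  expect_error(
    chi_square_test(rbind(c(0, 0), c(3, 4))),
    "margin"
  )
})

test_that("profile tables report counts, percentages, and paired tests", {
  set.seed(61)
  n <- 120
  assignments <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:n),
    cluster = rep(1:3, each = 40)
  )
  covariates <- tibble::tibble(
    participant_id = assignments$participant_id,
    sex = sample(c("women", "men"), n, replace = TRUE),
    age = rnorm(n, 50, 5)
  )
  ds <- tibble::tibble(
    participant_id = rep(assignments$participant_id, 2),
    day_type = rep(c("workday", "overall"), each = n),
    scope = "whole_day",
    wear_min = 4500, sb_min = 2700, lipa_min = 1500, mvpa_min = 300,
    wear_min_day = 900,
    sb_min_day = 540 + rep(c(0, 30, 60), each = 40) + rnorm(2 * n, sd = 10),
    sb_pct = 60 + rep(c(0, 3, 6), each = 40) + rnorm(2 * n),
    lipa_pct = 30, mvpa_pct = 10, breaks = 400,
    breaks_per_sed_hour = 8, n_days_pooled = 5
  )
  domain <- tibble::tibble(
    participant_id = rep(assignments$participant_id, 2),
    day_type = "workday",
    domain = rep(c("tv", "pc"), each = n),
    minutes = c(rnorm(n, 100, 20), c(rnorm(n - 10, 60, 20), rep(NA, 10)))
  )
  tabs <- build_profile_tables(
    assignments, covariates, ds, domain
  )
  ch <- tabs$characteristics
  expect_setequal(unique(ch$variable), c("sex", "age"))
  sex_rows <- ch[ch$variable == "sex", ]
  expect_equal(sum(sex_rows$n), n)
  # percentages are column percentages to 1 d.p.
  expect_true(all(abs(
    tapply(sex_rows$pct, sex_rows$cluster, sum) - 100
  ) < 0.11))
  bh <- tabs$behavior
  expect_setequal(unique(bh$day_type), c("workday", "overall"))
  sbp <- bh[bh$metric == "sb_pct" & bh$day_type == "workday", ]
  expect_lt(sbp$p[1], 0.001)
  expect_match(sbp$significant_pairs[1], "1<3")
  dom <- tabs$domains
  expect_equal(unique(dom$n_listwise[dom$domain == "pc"]), n - 10)
  expect_equal(unique(dom$n_listwise[dom$domain == "tv"]), n)
})

test_that("single-cluster and single-level inputs degrade gracefully", {
  assignments <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:20), cluster = 1
  )
  covariates <- tibble::tibble(
    participant_id = assignments$participant_id,
    sex = rep(c("women", "men"), 10),
    region = "urban"
  )
  expect_message(
    tabs <- build_profile_tables(assignments, covariates),
    "single level"
  )
  expect_true(all(is.na(tabs$characteristics$p)))
  expect_false("region" %in% tabs$characteristics$variable)
})

test_that("null cluster differences rarely reach significance", {
  set.seed(67)
  n <- 80
  assignments <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:n), cluster = rep(1:2, each = n / 2)
  )
  any_sig <- vapply(1:100, function(s) {
    covariates <- tibble::tibble(
      participant_id = assignments$participant_id,
      sex = sample(c("women", "men"), n, replace = TRUE)
    )
    tabs <- build_profile_tables(assignments, covariates)
    any(tabs$characteristics$p < 0.05, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(!any_sig), 0.9)
})
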