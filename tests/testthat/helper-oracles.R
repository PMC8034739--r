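# Independent oracles and fixture builders used across the suite. The
# oracles deliberately use naive enumeration so they share no code with the
# implementations they check.

make_epochs <- function(mets, id = "a", start = "2014-06-02 06:00") {
  tibble::tibble(
    participant_id = id,
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_along(mets) - 1) * 60,
    mets = mets
  )
}

# Brute-force non-wear oracle: mark the union of every window of >= 60
# epochs containing no value > 1.0 and at most two values in (0.9, 1.0].
oracle_nonwear <- function(mets, min_len = 60L, allowance = 2L) {
  n <- length(mets)
  mask <- logical(n)
  for (i in seq_len(n)) {
    tol <- 0L
    j <- i
    while (j <= n) {
      if (mets[j] > 1.0) break
      if (mets[j] > 0.9) {
        tol <- tol + 1L
        if (tol > allowance) break
      }
      j <- j + 1L
    }
    last <- j - 1L
    if (last - i + 1L >= min_len) mask[i:last] <- TRUE
  }
  mask
}

# Random METs series with alternating active and device-off regimes, so
# qualifying non-wear windows and near-threshold values both occur.
random_mets_series <- function(n) {
  mets <- numeric(0)
  off <- runif(1) < 0.5
  while (length(mets) < n) {
    len <- 1L + stats::rgeom(1L, if (off) 1 / 90 else 1 / 30)
    vals <- if (off) {
      sample(
        c(0.3, 0.8, 0.9, 0.95, 1.0, 1.05),
        len, replace = TRUE,
        prob = c(0.4, 0.2, 0.15, 0.1, 0.1, 0.05)
      )
    } else {
      runif(len, 1.1, 4)
    }
    mets <- c(mets, vals)
    off <- !off
  }
  mets[seq_len(n)]
}

# Greedy brute-force Ward: at each step merge the pair of clusters whose
# union minimally increases total within-cluster SS. Returns the partition
# after each merge plus the cost increments.
oracle_ward <- function(x) {
  x <- as.matrix(x)
  clusters <- as.list(seq_len(nrow(x)))
  ss <- function(rows) {
    xi <- x[rows, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }
  partitions <- list()
  costs <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    best_cost <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_len(a - 1L)) {
        cost <- ss(c(clusters[[a]], clusters[[b]])) -
          ss(clusters[[a]]) - ss(clusters[[b]])
        if (cost < best_cost) {
          best_cost <- cost
          best <- c(a, b)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    costs <- c(costs, best_cost)
    membership <- integer(nrow(x))
    for (g in seq_along(clusters)) membership[clusters[[g]]] <- g
    partitions <- c(partitions, list(membership))
  }
  list(partitions = partitions, costs = costs)
}

# Canonical form of a partition (cluster ids by order of first appearance),
# so partitions can be compared up to relabeling.
canonical_partition <- function(membership) {
  match(membership, unique(membership))
}

# Exhaustive best 2-partition within-SS for small n.
oracle_best2_ss <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  ss <- function(rows) {
    xi <- x[rows, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }
  best <- Inf
  for (mask in seq_len(2^(n - 1) - 1)) {
    g1 <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    g2 <- setdiff(seq_len(n), g1)
    best <- min(best, ss(g1) + ss(g2))
  }
  best
}

# A minimal archetype set with well-separated means for recovery tests:
# centers on a scaled simplex so every pairwise separation is >= `sep` SDs.
separated_archetypes <- function(sep = 4, sd = 8) {
  base <- rep(100, 6)
  shift <- sep * sd
  mk <- function(name, delta) {
    archetype_profile(
      name,
      vl_mean = base + delta, vl_sd = rep(sd, 6),
      day_sb_pct = c(60, 60)
    )
  }
  list(
    a = mk("a", c(0, 0, 0, 0, 0, 0)),
    b = mk("b", c(shift, 0, 0, 0, 0, 0)),
    c = mk("c", c(0, shift, 0, 0, 0, 0)),
    d = mk("d", c(0, 0, shift, 0, 0, 0))
  )
}

table1_counts <- function() {
  list(
    sex = rbind(women = c(47, 24, 9, 29), men = c(60, 37, 10, 13)),
    income = rbind(low = c(37, 17, 1, 19), high = c(70, 44, 18, 23)),
    sleep = rbind(short = c(65, 22, 7, 14), long = c(42, 39, 12, 28)),
    marital = rbind(married = c(81, 49, 14, 32), single = c(26, 12, 5, 10))
  )
}
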