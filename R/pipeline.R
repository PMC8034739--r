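#' Run the full typology pipeline
#'
#' Executes the complete analysis chain on an epoch-level cohort: non-wear
#' detection, per-day metrics, accelerometer eligibility, missing-data
#' filters, day-type pooling, variation-level features, two-step clustering
#' (Ward, then deterministic k-means), and cluster profiling. Inputs may be
#' in-memory tibbles or CSV paths. A manifest records the count retained at
#' each filter stage; the counts telescope
#' (`n_input - sum(exclusions) = n_analyzed`).
#'
#' @param epochs Epoch tibble or path to an epoch CSV.
#' @param diary Diary tibble or path to a diary CSV.
#' @param covariates Optional covariate tibble (`participant_id` + columns;
#'   rows with any missing value are excluded and counted).
#' @param work_sb Optional work-domain self-report tibble
#'   (`participant_id`, `work_sb_min`; `NA` rows are excluded and counted).
#' @param domain_sb Optional long domain self-report tibble for profiling.
#' @param k Number of clusters, or `NULL` to select via [select_k()].
#' @param k_range Candidate k range for selection.
#' @param pooling Day-type pooling convention (see
#'   [pool_daytype_metrics()]).
#' @param output_dir Optional directory; when given, stage outputs are
#'   written as CSV/JSON (day metrics, eligibility, features, assignments,
#'   centroids, dendrogram, manifest).
#'
#' @return A `sed_pipeline_result` list: `day_metrics`, `eligibility`,
#'   `daytype_summary`, `features`, `tree`, `model`, `assignments`,
#'   `profiles`, `manifest`.
#' @export
run_pipeline <- function(epochs, diary, covariates = NULL, work_sb = NULL,
                         domain_sb = NULL, k = NULL, k_range = c(2L, 8L),
                         pooling = "pooled", output_dir = NULL) {
  if (is.character(epochs)) epochs <- read_epoch_csv(epochs)
  if (is.character(diary)) diary <- read_diary_csv(diary)

  epochs <- detect_nonwear(epochs)
  day_metrics <- compute_day_metrics(epochs, diary)
  eligibility <- assess_eligibility(day_metrics)

  n_input <- length(unique(day_metrics$participant_id))
  keep <- eligibility$participant_id[eligibility$eligible]
  n_wear_excl <- n_input - length(keep)

  n_ws_excl <- 0L
  if (!is.null(work_sb)) {
    ok <- work_sb$participant_id[!is.na(work_sb$work_sb_min)]
    kept <- intersect(keep, ok)
    n_ws_excl <- length(keep) - length(kept)
    keep <- kept
  }
  n_cov_excl <- 0L
  if (!is.null(covariates)) {
    ok <- covariates$participant_id[
      complete.cases(dplyr::select(covariates, -"participant_id"))
    ]
    kept <- intersect(keep, ok)
    n_cov_excl <- length(keep) - length(kept)
    keep <- kept
  }
  if (length(keep) == 0L) {
    abort(paste0(
      "zero eligible participants (input ", n_input,
      "; wear exclusions ", n_wear_excl, ")"
    ))
  }

  dm_kept <- dplyr::filter(day_metrics, .data$participant_id %in% keep)
  daytype_summary <- dplyr::bind_rows(
    pool_daytype_metrics(dm_kept, method = pooling),
    pool_overall_metrics(dm_kept)
  )
  features <- build_feature_matrix(
    dplyr::filter(daytype_summary, .data$day_type != "overall")
  )
  n_feat_excl <- attr(features, "n_dropped") %||% 0L

  tree <- ward_linkage(features)
  if (is.null(k)) k <- select_k(tree, k_range[1], k_range[2])
  model <- kmeans_refine(features, tree, k)
  assignments <- tibble::tibble(
    participant_id = features$participant_id,
    cluster = unname(model$assignments)
  )
  profiles <- build_profile_tables(
    assignments,
    covariates = covariates, daytype_summary = daytype_summary,
    domain_sb = domain_sb
  )

  manifest <- list(
    counts = tibble::tibble(
      stage = c(
        "input", "insufficient_accelerometer_data",
        "missing_work_domain_self_report", "missing_covariates",
        "undefined_features", "analyzed"
      ),
      n_excluded = c(
        NA, n_wear_excl, n_ws_excl, n_cov_excl, n_feat_excl, NA
      ),
      n_remaining = c(
        n_input, n_input - n_wear_excl,
        n_input - n_wear_excl - n_ws_excl,
        n_input - n_wear_excl - n_ws_excl - n_cov_excl,
        nrow(features), nrow(features)
      )
    ),
    k = k, pooling = pooling
  )

  result <- structure(
    list(
      day_metrics = day_metrics, eligibility = eligibility,
      daytype_summary = daytype_summary, features = features,
      tree = tree, model = model, assignments = assignments,
      profiles = profiles, manifest = manifest
    ),
    class = "sed_pipeline_result"
  )
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  readr::write_csv(result$day_metrics, p("day_metrics.csv"))
  readr::write_csv(result$eligibility, p("eligibility.csv"))
  readr::write_csv(result$features, p("features.csv"))
  readr::write_csv(result$assignments, p("assignments.csv"))
  readr::write_csv(
    tibble::as_tibble(result$model$centroids) |>
      dplyr::mutate(cluster = dplyr::row_number(), .before = 1),
    p("centroids.csv")
  )
  write_ward_json(result$tree, p("dendrogram.json"))
  jsonlite::write_json(
    list(
      counts = result$manifest$counts, k = result$manifest$k,
      pooling = result$manifest$pooling,
      package_version = as.character(utils::packageVersion("sedclust"))
    ),
    p("manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(output_dir)
}

#' @export
print.sed_pipeline_result <- function(x, ...) {
  cat("<sed_pipeline_result>\n")
  print(x$manifest$counts)
  print(x$model)
  invisible(x)
}
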