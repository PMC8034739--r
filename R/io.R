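#' Read a minute-epoch METs CSV
#'
#' Expects columns `participant_id`, `timestamp` (ISO-8601, minute
#' resolution, epoch start), `mets`. Series are returned sorted by
#' participant and time. Duplicate (participant, timestamp) pairs, minute
#' gaps inside a calendar day, unparseable timestamps, and negative METs
#' raise errors naming the first offender.
#'
#' @param path CSV file path.
#' @return Epoch tibble (`participant_id`, `timestamp` POSIXct UTC,
#'   `mets`).
#' @export
read_epoch_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      mets = readr::col_double()
    )
  )
  if (!all(c("participant_id", "timestamp", "mets") %in% names(raw))) {
    abort("epoch CSV must have columns participant_id, timestamp, mets")
  }
  if (nrow(raw) == 0L) {
    warn("epoch CSV is empty")
    return(raw)
  }
  if (anyNA(raw$timestamp)) abort("unparseable timestamp in epoch CSV")
  if (any(raw$mets < 0, na.rm = TRUE)) {
    abort("negative METs value in epoch CSV")
  }
  raw <- dplyr::arrange(raw, .data$participant_id, .data$timestamp)
  dup <- raw |>
    dplyr::count(.data$participant_id, .data$timestamp) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0(
      "duplicate epoch for participant ", dup$participant_id[1],
      " at ", format(dup$timestamp[1], tz = "UTC")
    ))
  }
  gaps <- raw |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      gap_at = .data$timestamp[
        which(diff(as.numeric(.data$timestamp)) != 60)[1] + 1L
      ][1],
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$gap_at))
  if (nrow(gaps) > 0L) {
    abort(paste0(
      "non-contiguous minutes within a day for participant ",
      gaps$participant_id[1], " near ", format(gaps$gap_at[1], tz = "UTC")
    ))
  }
  raw
}

#' Read a day-type diary CSV
#'
#' Columns: `participant_id`, `date` (ISO), `day_type` (`workday` or
#' `non_workday`; `non-workday` is normalized).
#'
#' @param path CSV file path.
#' @return Diary tibble.
#' @export
read_diary_csv <- function(path) {
  d <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      date = readr::col_date(),
      day_type = readr::col_character()
    )
  )
  d$day_type <- gsub("-", "_", d$day_type)
  bad <- setdiff(unique(d$day_type), DAY_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown day_type value(s): ", paste(bad, collapse = ", ")))
  }
  d
}

#' Write epoch series to CSV
#'
#' @param epochs Epoch tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(epochs, path) {
  out <- dplyr::mutate(
    epochs,
    timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  readr::write_csv(out[c("participant_id", "timestamp", "mets")], path)
  invisible(path)
}

#' Serialize a Ward tree to JSON
#'
#' Stores the merge list and merge-cost heights.
#'
#' @param tree A [ward_linkage()] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ward_json <- function(tree, path) {
  jsonlite::write_json(
    list(
      n_leaves = tree$n_leaves, merge = tree$merge, height = tree$height,
      labels = tree$labels
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
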