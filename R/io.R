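#' Read a raw EDA recording from CSV
#'
#' Recordings are two-column comma-separated files with a header,
#' `time_s,eda_uS`: time in seconds (strictly increasing, possibly irregular)
#' and skin conductance in microsiemens. An optional `subject_id` column is
#' carried through if present; otherwise the file stem is used.
#'
#' @param path Path to a recording CSV.
#' @param subject_id Subject identifier; defaults to the `subject_id` column
#'   when present, else the file name without extension.
#' @return A tibble with columns `subject_id`, `time_s`, `eda_uS`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_eda_recording(tibble::tibble(
#'   subject_id = "s1", time_s = c(0, 0.5), eda_uS = c(1, 1.1)), f)
#' read_eda_recording(f)
read_eda_recording <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("recording file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "eda_uS")
  if (!all(need %in% names(df))) {
    stop("recording file must have columns time_s,eda_uS: ", path, call. = FALSE)
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$eda_uS))
  if (length(bad)) {
    stop("non-numeric or non-finite recording row at data line ", bad[1],
         " in ", path, call. = FALSE)
  }
  sid <- subject_id %||% (if ("subject_id" %in% names(df)) as.character(df$subject_id[1])
                          else sub("\\.[^.]*$", "", basename(path)))
  rec <- tibble(subject_id = sid, time_s = as.numeric(df$time_s),
                eda_uS = as.numeric(df$eda_uS))
  validate_recording(rec)
  rec
}

#' Write a raw EDA recording to CSV
#'
#' @param record Tibble with columns `time_s`, `eda_uS` (and optionally
#'   `subject_id`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eda_recording <- function(record, path) {
  validate_recording(record)
  cols <- intersect(c("subject_id", "time_s", "eda_uS"), names(record))
  readr::write_csv(record[cols], path, progress = FALSE)
  invisible(path)
}

validate_recording <- function(record) {
  stopifnot(is.data.frame(record), all(c("time_s", "eda_uS") %in% names(record)))
  if (nrow(record) < 2L) stop("recording must have at least 2 samples", call. = FALSE)
  if (any(!is.finite(record$time_s)) || any(!is.finite(record$eda_uS))) {
    stop("recording contains non-finite values", call. = FALSE)
  }
  if (any(diff(record$time_s) <= 0)) {
    i <- which(diff(record$time_s) <= 0)[1]
    stop("timestamps must be strictly increasing (violated at row ", i + 1, ")",
         call. = FALSE)
  }
  if (any(record$eda_uS < 0)) stop("conductance must be nonnegative", call. = FALSE)
  invisible(record)
}

#' Read stimulus events from CSV
#'
#' Events are `(subject_id, time_s)` rows; output is sorted by subject then
#' event time. Negative event times are rejected.
#'
#' @param path Path to an events CSV with columns `subject_id`, `time_s`.
#' @return A tibble with columns `subject_id`, `time_s`, sorted.
#' @export
read_stimulus_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          subject_id = readr::col_character(),
                          time_s = readr::col_double()))
  if (nrow(df) == 0L) {
    return(tibble(subject_id = character(), time_s = numeric()))
  }
  if (!all(c("subject_id", "time_s") %in% names(df))) {
    stop("event file must have columns subject_id,time_s: ", path, call. = FALSE)
  }
  if (any(!is.finite(df$time_s))) stop("non-numeric event time in ", path, call. = FALSE)
  if (any(df$time_s < 0)) stop("negative event times in ", path, call. = FALSE)
  df %>% select(all_of(c("subject_id", "time_s"))) %>%
    arrange(.data$subject_id, .data$time_s)
}

#' Write stimulus events to CSV
#'
#' @param events Tibble with columns `subject_id`, `time_s`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_events <- function(events, path) {
  stopifnot(all(c("subject_id", "time_s") %in% names(events)))
  readr::write_csv(events[c("subject_id", "time_s")], path, progress = FALSE)
  invisible(path)
}

#' Write an index-series table to CSV
#'
#' @param indices Tibble as returned by [eda_indices()] or
#'   [run_stream_simulation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index_series <- function(indices, path) {
  readr::write_csv(indices, path, progress = FALSE)
  invisible(path)
}

#' Read an index-series table from CSV
#' @param path Path to an index CSV.
#' @return A tibble.
#' @export
read_index_series <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# JSON sidecar recording the configuration and seed of a run, next to `path`.
write_run_sidecar <- function(path, config, seed = NULL) {
  side <- paste0(path, ".run.json")
  jsonlite::write_json(
    list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, config = config),
    side, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(side)
}
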