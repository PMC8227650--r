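#' Extract painless/pain segment features around stimulus events
#'
#' For each stimulus, the `seg_len` seconds before the stimulus form the
#' painless segment and the `seg_len` seconds after it the pain segment
#' (half-open windows: the stimulus sample belongs to the pain segment only).
#' Event times are snapped to the nearest index sample. Per segment, the mean
#' and maximum of each of the three indices give the 6 features. Events too
#' close to a boundary are skipped (not clipped), so every window has exactly
#' `seg_len * rate` samples.
#'
#' @param indices Tibble with columns `time_s`, `tvsymp`, `mtvsymp`, `dpheda`
#'   at a uniform rate (from [eda_indices()]); a column named `emitted_at_s`
#'   is accepted in place of `time_s` for streamed series.
#' @param events Tibble with columns `subject_id`, `time_s`.
#' @param seg_len Segment length in seconds (default 5).
#' @param subject_id Subject identifier for the rows (defaults to the single
#'   id in `events`).
#' @param dataset Dataset tag (e.g. `"TG"`, `"EP"`, `"synthetic"`).
#' @return Tibble with columns `subject_id`, `dataset`, `event_time_s`,
#'   `label` (0 painless, 1 pain) and the six features `tvsymp_mean`,
#'   `tvsymp_max`, `mtvsymp_mean`, `mtvsymp_max`, `dpheda_mean`,
#'   `dpheda_max`. Two rows per usable event.
#' @export
extract_segments <- function(indices, events, seg_len = 5,
                             subject_id = NULL, dataset = "synthetic") {
  if ("emitted_at_s" %in% names(indices) && !"time_s" %in% names(indices)) {
    indices <- dplyr::rename(indices, time_s = "emitted_at_s")
  }
  need <- c("time_s", "tvsymp", "mtvsymp", "dpheda")
  stopifnot(all(need %in% names(indices)))
  rate <- series_rate(indices$time_s)
  w <- as.integer(round(seg_len * rate))
  n <- nrow(indices)
  sid <- subject_id %||% {
    u <- unique(events$subject_id)
    if (length(u) > 1) stop("events contain multiple subjects; pass subject_id",
                            call. = FALSE)
    if (length(u)) u else NA_character_
  }
  ev <- events$time_s
  rows <- list(); skipped <- 0L
  for (te in ev) {
    i0 <- which.min(abs(indices$time_s - te))   # stimulus sample (1-based)
    if (i0 - w < 1L || i0 + w - 1L > n) { skipped <- skipped + 1L; next }
    pre <- indices[(i0 - w):(i0 - 1L), ]
    post <- indices[i0:(i0 + w - 1L), ]
    feat <- function(seg) {
      c(tvsymp_mean = mean(seg$tvsymp), tvsymp_max = max(seg$tvsymp),
        mtvsymp_mean = mean(seg$mtvsymp), mtvsymp_max = max(seg$mtvsymp),
        dpheda_mean = mean(seg$dpheda), dpheda_max = max(seg$dpheda))
    }
    for (lab in 0:1) {
      f <- feat(if (lab == 0) pre else post)
      rows[[length(rows) + 1L]] <- tibble(
        subject_id = sid, dataset = dataset, event_time_s = te,
        label = lab, !!!as.list(f))
    }
  }
  if (skipped > 0L) {
    warning(skipped, " event(s) skipped: too close to the recording boundary",
            call. = FALSE)
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble(subject_id = character(), dataset = character(),
           event_time_s = numeric(), label = integer(),
           tvsymp_mean = numeric(), tvsymp_max = numeric(),
           mtvsymp_mean = numeric(), mtvsymp_max = numeric(),
           dpheda_mean = numeric(), dpheda_max = numeric())
}

#' Pool segment feature tables from several datasets
#'
#' Concatenates per-dataset feature tables, preserving subject and dataset
#' identity. Subject ids must be disjoint across dataset tags (the two
#' experiments recruited non-overlapping subjects); duplicates are an error.
#'
#' @param tables A list of segment feature tables (from [extract_segments()]).
#' @return A single pooled tibble.
#' @export
pool_datasets <- function(tables) {
  tables <- tables[vapply(tables, nrow, 1L) > 0]
  if (!length(tables)) {
    return(tibble(
      subject_id = character(), dataset = character(),
      event_time_s = numeric(), label = integer(),
      tvsymp_mean = numeric(), tvsymp_max = numeric(),
      mtvsymp_mean = numeric(), mtvsymp_max = numeric(),
      dpheda_mean = numeric(), dpheda_max = numeric()))
  }
  pooled <- dplyr::bind_rows(tables)
  by_tag <- unique(pooled[c("subject_id", "dataset")])
  dup <- by_tag$subject_id[duplicated(by_tag$subject_id)]
  if (length(dup)) {
    stop("duplicate subject id(s) across dataset tags: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  pooled
}

feature_names <- function() {
  c("tvsymp_mean", "tvsymp_max", "mtvsymp_mean",
    "mtvsymp_max", "dpheda_mean", "dpheda_max")
}
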