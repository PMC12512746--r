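#' Read and validate acoustic telemetry tables
#'
#' Reads a detections CSV together with the receiver-station and tag-deployment
#' tables, validates their schemas, normalises all timestamps to UTC and
#' returns the three tables sorted and ready for filtering. Detections that
#' reference a station absent from the station table are, by default, dropped
#' with a warning; detections of tags absent from the tag table are kept with
#' `species`/`sex` set to `"unknown"`/`"U"` and a warning, and are excluded
#' from species and sex strata downstream.
#'
#' Expected columns: detections `tag_id, station_id, datetime, qc_flag`
#' (optional `species`, `sex`); stations `station_id, latitude, longitude,
#' reef_system, atoll` (optional `detection_range_m`, default 300); tags
#' `tag_id, species, sex, total_length_cm, deploy_datetime, deploy_station`.
#' `datetime` may carry any ISO-8601 offset; it is stored as UTC.
#'
#' @param path Path to the detections CSV.
#' @param station_path Path to the receiver-station CSV.
#' @param tag_path Path to the tag-deployment CSV.
#' @param unknown_station One of `"drop"` (default; drop the rows and warn),
#'   `"keep"`, or `"error"`.
#' @return A list with elements `detections`, `stations` and `tags`, each a
#'   tibble. Detections are sorted by (`tag_id`, `timestamp`) and carry
#'   `species` and `sex` joined from the tag table.
#' @export
read_detections <- function(path, station_path, tag_path,
                            unknown_station = c("drop", "keep", "error")) {
  unknown_station <- match.arg(unknown_station)
  for (p in c(path, station_path, tag_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  stations <- read_station_table(station_path)
  tags <- read_tag_table(tag_path)

  det <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(det, c("tag_id", "station_id", "datetime", "qc_flag"), "detections table")
  ts <- readr::parse_datetime(det$datetime)
  bad <- which(is.na(ts) & !is.na(det$datetime))
  if (length(bad) > 0) {
    abort(sprintf(
      "unparseable timestamp%s in detections at data row%s: %s (e.g. \"%s\")",
      if (length(bad) > 1) "s" else "", if (length(bad) > 1) "s" else "",
      paste(head(bad, 5), collapse = ", "), det$datetime[bad[1]]
    ), class = "reefnet_parse_error")
  }
  detections <- tibble(
    tag_id = det$tag_id,
    station_id = det$station_id,
    timestamp = as_utc(ts),
    qc_flag = as.integer(det$qc_flag)
  )

  unknown <- setdiff(unique(detections$station_id), stations$station_id)
  if (length(unknown) > 0) {
    msg <- sprintf("detections reference %d unknown station id(s): %s",
                   length(unknown), paste(head(unknown, 5), collapse = ", "))
    if (unknown_station == "error") abort(msg, class = "reefnet_unknown_station")
    warn(msg)
    if (unknown_station == "drop") {
      detections <- filter(detections, !.data$station_id %in% unknown)
    }
  }

  detections <- left_join(detections,
                          select(tags, "tag_id", "species", "sex"),
                          by = "tag_id")
  untagged <- is.na(detections$species)
  if (any(untagged)) {
    warn(sprintf("%d detections from %d tag(s) absent from the tag table; kept with species/sex unknown",
                 sum(untagged), length(unique(detections$tag_id[untagged]))))
    detections$species[untagged] <- "unknown"
    detections$sex[untagged] <- "U"
  }
  detections <- arrange(detections, .data$tag_id, .data$timestamp)
  list(detections = detections, stations = stations, tags = tags)
}

#' @rdname read_detections
#' @export
read_station_table <- function(station_path) {
  st <- readr::read_csv(station_path, col_types = readr::cols(), progress = FALSE)
  check_columns(st, c("station_id", "latitude", "longitude", "reef_system", "atoll"),
                "station table")
  if (!"detection_range_m" %in% names(st)) st$detection_range_m <- 300
  if (any(abs(st$latitude) > 90) || any(abs(st$longitude) > 180)) {
    abort("station coordinates out of range", class = "reefnet_schema_error")
  }
  as_tibble(st)
}

#' @rdname read_detections
#' @export
read_tag_table <- function(tag_path) {
  tg <- readr::read_csv(tag_path, col_types = readr::cols(.default = readr::col_guess()),
                        progress = FALSE)
  check_columns(tg, c("tag_id", "species", "sex"), "tag table")
  tg$tag_id <- as.character(tg$tag_id)
  tg$sex <- ifelse(is.na(tg$sex) | !tg$sex %in% c("F", "M"), "U", tg$sex)
  if (anyDuplicated(tg$tag_id)) {
    abort("duplicate tag_id in tag table", class = "reefnet_schema_error")
  }
  as_tibble(tg)
}

#' Write a telemetry table as RFC-4180 CSV
#'
#' Timestamp columns are serialised as ISO-8601 UTC so re-reading a written
#' table is lossless.
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_telemetry_csv <- function(x, path) {
  x <- mutate(x, across(dplyr::where(~ inherits(.x, "POSIXct")),
                        ~ format(as_utc(.x), "%Y-%m-%dT%H:%M:%SZ")))
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Keep detections with accepted quality-control flags
#'
#' Databases of archived telemetry flag each detection with a QC code
#' (1 = valid, 2 = likely valid, larger codes = suspect/invalid). The analysis
#' keeps codes 1 and 2 by default.
#'
#' @param detections Detection tibble with a `qc_flag` column.
#' @param allowed_flags Integer vector of flags to keep (default `c(1, 2)`).
#' @return The detections with disallowed rows removed; row order preserved.
#' @export
apply_qc_filter <- function(detections, allowed_flags = c(1L, 2L)) {
  if (any(is.na(detections$qc_flag))) {
    abort("qc_flag must be populated for every detection")
  }
  out <- filter(detections, .data$qc_flag %in% allowed_flags)
  if (nrow(out) == 0 && nrow(detections) > 0) {
    warn("QC filter removed every detection")
  }
  out
}

#' Drop short or sparse individual tracks
#'
#' Removes every detection of a tag whose track spans fewer than `min_days`
#' days (last minus first detection) or has fewer than `min_detections`
#' detections. Both thresholds are inclusive: a track of exactly 7.0 days or
#' exactly 50 detections is kept. Short, sparse tracks are typically biased
#' toward the tagging site (animals leaving the array shortly after release).
#'
#' @param detections QC-filtered detection tibble.
#' @param min_days Minimum track duration in days (default 7).
#' @param min_detections Minimum number of detections (default 50).
#' @return Detections of qualifying tags only.
#' @export
apply_track_minimums <- function(detections, min_days = 7, min_detections = 50L) {
  if (nrow(detections) == 0) return(detections)
  keep <- detections %>%
    group_by(.data$tag_id) %>%
    summarise(
      span_days = as.numeric(difftime(max(.data$timestamp), min(.data$timestamp),
                                      units = "days")),
      n_det = dplyr::n(), .groups = "drop"
    ) %>%
    filter(.data$span_days >= min_days, .data$n_det >= min_detections) %>%
    pull("tag_id")
  filter(detections, .data$tag_id %in% keep)
}

#' Deduplicate dense detections at each receiver
#'
#' Per (tag, station), keeps the first detection and then each subsequent
#' detection only if it falls at least `window_s` seconds after the last kept
#' detection at that station (greedy rolling window, so the operation is
#' idempotent). Detections of the same tag at different stations are never
#' suppressed. This standardises the data and removes false detections caused
#' by transmission collisions.
#'
#' @param detections Detection tibble sorted by (`tag_id`, `timestamp`).
#' @param window_s Minimum within-station spacing in seconds (default 300).
#' @return Deduplicated detections, sorted by (`tag_id`, `timestamp`).
#' @export
deduplicate_detections <- function(detections, window_s = 300L) {
  if (nrow(detections) == 0) return(detections)
  detections <- arrange(detections, .data$tag_id, .data$timestamp)
  keep <- detections %>%
    group_by(.data$tag_id, .data$station_id) %>%
    mutate(keep_row = greedy_keep(as.numeric(.data$timestamp), window_s)) %>%
    ungroup() %>%
    pull("keep_row")
  detections[keep, , drop = FALSE]
}

# greedy rolling rule: keep t[i] iff t[i] - last_kept >= window
greedy_keep <- function(t, window_s) {
  n <- length(t)
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (t[i] - last >= window_s || is.infinite(last)) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  keep
}

#' Run the full detection-filtering sequence
#'
#' Applies the three filters in order: QC flags, track minimums, then
#' per-receiver deduplication. Track-minimum detection counts therefore use
#' pre-deduplication detections by default; set
#' `order = "qc_dedup_minimums"` to count after deduplication instead.
#'
#' @inheritParams apply_qc_filter
#' @inheritParams apply_track_minimums
#' @inheritParams deduplicate_detections
#' @param order Filter composition order.
#' @return Filtered detection tibble.
#' @export
filter_detections <- function(detections, allowed_flags = c(1L, 2L),
                              min_days = 7, min_detections = 50L,
                              window_s = 300L,
                              order = c("qc_minimums_dedup", "qc_dedup_minimums")) {
  order <- match.arg(order)
  out <- apply_qc_filter(detections, allowed_flags)
  if (order == "qc_minimums_dedup") {
    out <- apply_track_minimums(out, min_days, min_detections)
    out <- deduplicate_detections(out, window_s)
  } else {
    out <- deduplicate_detections(out, window_s)
    out <- apply_track_minimums(out, min_days, min_detections)
  }
  out
}
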