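test_that("reading sorts, normalises timezones and round-trips through CSV", {
  dir <- withr::local_tempdir()
  det_csv <- file.path(dir, "det.csv")
  # mixed input order, mixed ISO-8601 offsets
  writeLines(c(
    "tag_id,station_id,datetime,qc_flag",
    "T2,S1,2013-05-01T02:00:00Z,1",
    "T1,S2,2013-05-01T10:00:00+10:00,1",   # 00:00 UTC
    "T1,S1,2013-05-01T01:00:00Z,2"
  ), det_csv)
  st_csv <- file.path(dir, "st.csv")
  writeLines(c(
    "station_id,latitude,longitude,reef_system,atoll",
    "S1,-14.1,121.8,SynthReef,A1",
    "S2,-14.2,121.9,SynthReef,A1"
  ), st_csv)
  tag_csv <- file.path(dir, "tags.csv")
  writeLines(c(
    "tag_id,species,sex,total_length_cm,deploy_datetime,deploy_station",
    "T1,grey_reef_shark,F,140,2013-04-01T00:00:00Z,S1",
    "T2,red_bass,U,60,2013-04-01T00:00:00Z,S2"
  ), tag_csv)

  res <- read_detections(det_csv, st_csv, tag_csv)
  expect_equal(nrow(res$detections), 3)
  expect_equal(res$detections$tag_id, c("T1", "T1", "T2"))
  # the +10:00 offset row is the earliest UTC instant for T1
  expect_equal(res$detections$station_id[1], "S2")
  expect_equal(attr(res$detections$timestamp, "tzone"), "UTC")
  expect_equal(res$stations$detection_range_m, c(300, 300))

  # writing and re-reading the detections is idempotent
  out_csv <- file.path(dir, "out.csv")
  write_telemetry_csv(dplyr::select(res$detections, tag_id, station_id,
                                    datetime = timestamp, qc_flag), out_csv)
  res2 <- read_detections(out_csv, st_csv, tag_csv)
  expect_equal(res2$detections, res$detections)
})

test_that("schema and parse failures are reported with context", {
  dir <- withr::local_tempdir()
  st_csv <- file.path(dir, "st.csv")
  writeLines(c("station_id,latitude,longitude,reef_system,atoll",
               "S1,-14.1,121.8,R,A1"), st_csv)
  tag_csv <- file.path(dir, "tags.csv")
  writeLines(c("tag_id,species,sex", "T1,x,F"), tag_csv)

  bad_col <- file.path(dir, "bad1.csv")
  writeLines(c("tag_id,station_id,qc_flag", "T1,S1,1"), bad_col)
  expect_error(read_detections(bad_col, st_csv, tag_csv),
               "datetime", class = "reefnet_schema_error")

  bad_ts <- file.path(dir, "bad2.csv")
  writeLines(c("tag_id,station_id,datetime,qc_flag",
               "T1,S1,2013-05-01T00:00:00Z,1",
               "T1,S1,not-a-date,1"), bad_ts)
  expect_error(read_detections(bad_ts, st_csv, tag_csv),
               "row.*2|2.*not-a-date", class = "reefnet_parse_error")

  unk <- file.path(dir, "unk.csv")
  writeLines(c("tag_id,station_id,datetime,qc_flag",
               "T1,S9,2013-05-01T00:00:00Z,1",
               "T1,S1,2013-05-01T01:00:00Z,1"), unk)
  expect_warning(res <- read_detections(unk, st_csv, tag_csv), "unknown station")
  expect_equal(res$detections$station_id, "S1")
})

test_that("QC filter keeps exactly the allowed flags and preserves order", {
  det <- make_detections("T1", "S1", (0:4) * 600, qc = c(1, 2, 3, 4, 1))
  out <- apply_qc_filter(det)
  expect_equal(out$qc_flag, c(1L, 2L, 1L))
  expect_equal(out$timestamp, det$timestamp[c(1, 2, 5)])

  all_valid <- make_detections("T1", "S1", (0:3) * 600, qc = 1L)
  expect_identical(apply_qc_filter(all_valid), all_valid)

  strict <- make_detections("T1", "S1", c(0, 600), qc = c(2L, 2L))
  expect_warning(empty <- apply_qc_filter(strict, allowed_flags = 1L),
                 "every detection")
  expect_equal(nrow(empty), 0)
})

test_that("track minimums are inclusive at both thresholds", {
  day <- 86400
  # 49 detections over 10 days: count fails
  sparse <- make_detections("T1", "S1", seq(0, 10 * day, length.out = 49))
  expect_equal(nrow(apply_track_minimums(sparse)), 0)

  # 60 detections spanning 6.99 days: duration fails
  short <- make_detections("T2", "S1", seq(0, 6.99 * day, length.out = 60))
  expect_equal(nrow(apply_track_minimums(short)), 0)

  # exactly 7.00 days and exactly 50 detections: both inclusive, kept
  exact <- make_detections("T3", "S1", seq(0, 7 * day, length.out = 50))
  expect_equal(nrow(apply_track_minimums(exact)), 50)

  # mixed table keeps only the qualifying tag
  mixed <- dplyr::bind_rows(sparse, exact)
  kept <- apply_track_minimums(mixed)
  expect_equal(unique(kept$tag_id), "T3")
  expect_equal(nrow(kept), 50)
})

test_that("track minimums are invariant to input row order", {
  day <- 86400
  det <- dplyr::bind_rows(
    make_detections("A", "S1", seq(0, 8 * day, length.out = 60)),
    make_detections("B", "S1", seq(0, 3 * day, length.out = 80))
  )
  shuffled <- det[sample.int(nrow(det)), ]
  a <- apply_track_minimums(det)
  b <- dplyr::arrange(apply_track_minimums(shuffled), tag_id, timestamp)
  expect_equal(dplyr::arrange(a, tag_id, timestamp), b)
})

test_that("deduplication follows the greedy rolling window and is idempotent", {
  # t = 0, 120, 400: 120 suppressed (120 < 300 after 0), 400 kept (>= 300)
  det <- make_detections("T1", "S1", c(0, 120, 400))
  out <- deduplicate_detections(det)
  expect_equal(as.numeric(out$timestamp - out$timestamp[1], units = "secs"),
               c(0, 400))

  # alternating stations: the two receivers keep independent clocks, so
  # detections at B never tighten A's window; with within-station gaps at
  # the window width nothing is removed
  alt <- make_detections("T1", rep(c("A", "B"), 10), (0:19) * 150)
  expect_equal(nrow(deduplicate_detections(alt)), 20)

  # idempotence and the spacing invariant on a dense random fixture
  set.seed(42)
  dense <- make_detections("T1", sample(c("A", "B"), 400, TRUE),
                           sort(sample.int(20000, 400)))
  once <- deduplicate_detections(dense)
  twice <- deduplicate_detections(once)
  expect_identical(once, twice)
  gaps <- once %>%
    dplyr::group_by(station_id) %>%
    dplyr::summarise(min_gap = min(c(Inf, diff(as.numeric(timestamp)))))
  expect_true(all(gaps$min_gap >= 300))
})

test_that("each filter's output is a subset of its input", {
  sim <- small_sim()
  det <- sim$detections
  qc <- apply_qc_filter(det)
  tm <- apply_track_minimums(qc)
  dd <- deduplicate_detections(tm)
  key <- function(d) paste(d$tag_id, d$station_id, d$timestamp, d$qc_flag)
  expect_true(all(key(qc) %in% key(det)))
  expect_true(all(key(tm) %in% key(qc)))
  expect_true(all(key(dd) %in% key(tm)))
  expect_identical(filter_detections(det), dd)
})
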