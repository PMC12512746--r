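#' Solar position (altitude and ascending flag)
#'
#' Computes the sun's altitude above the horizon using the NOAA low-precision
#' solar ephemeris (the equations behind the published NOAA solar calculator;
#' accuracy well within 0.3 degrees for recent decades). The ascending flag is
#' the sign of the altitude's time derivative, evaluated by central finite
#' difference over +/- 60 s.
#'
#' @param time POSIXct vector (any timezone; computed in UTC).
#' @param lat,lon Latitude and longitude in decimal degrees (vectorised,
#'   recycled against `time`).
#' @return A tibble with columns `time`, `altitude` (degrees) and `ascending`
#'   (logical).
#' @export
solar_position <- function(time, lat, lon) {
  time <- as_utc(as.POSIXct(time))
  stopifnot(all(abs(lat) <= 90))
  alt <- solar_altitude(as.numeric(time), lat, lon)
  asc <- solar_altitude(as.numeric(time) + 60, lat, lon) >
    solar_altitude(as.numeric(time) - 60, lat, lon)
  tibble(time = time, altitude = alt, ascending = asc)
}

# NOAA solar calculator equations; t is unix seconds (UTC). Vectorised.
solar_altitude <- function(t, lat, lon) {
  jd <- t / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  deg2rad <- pi / 180
  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(gmas * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * deg2rad) * 0.000289
  app <- gmls + eqctr - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * deg2rad)
  mobliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mobliq + 0.00256 * cos((125.04 - 1934.136 * jc) * deg2rad)
  decl <- asin(sin(obliq * deg2rad) * sin(app * deg2rad))
  vary <- tan(obliq / 2 * deg2rad)^2
  eqtime <- 4 / deg2rad * (
    vary * sin(2 * gmls * deg2rad) -
      2 * eeo * sin(gmas * deg2rad) +
      4 * eeo * vary * sin(gmas * deg2rad) * cos(2 * gmls * deg2rad) -
      0.5 * vary^2 * sin(4 * gmls * deg2rad) -
      1.25 * eeo^2 * sin(2 * gmas * deg2rad)
  )
  mins_utc <- (t %% 86400) / 60
  tst <- (mins_utc + eqtime + 4 * lon) %% 1440
  ha <- ifelse(tst / 4 < 0, tst / 4 + 180, tst / 4 - 180)
  coszen <- sin(lat * deg2rad) * sin(decl) +
    cos(lat * deg2rad) * cos(decl) * cos(ha * deg2rad)
  90 - acos(pmin(pmax(coszen, -1), 1)) / deg2rad
}

# altitude thresholds (degrees): astronomical night boundary, sunset with
# refraction + solar radius, morning golden-hour end
NIGHT_ALT <- -18
SUNSET_ALT <- -0.833
GOLDEN_ALT <- 6

#' Solar event times for one civil day
#'
#' Finds the four altitude-threshold crossings that delimit the diel periods:
#' `night_end` (sun ascending through -18 deg), `golden_hour_end` (ascending
#' through +6 deg), `sunset` (descending through -0.833 deg) and `night_start`
#' (descending through -18 deg). Crossings are bracketed on a 2-minute grid
#' over the local mean solar day and refined to under one second. At high
#' latitudes a threshold may never be crossed on a given day; the
#' corresponding event is returned as `NA` (event undefined).
#'
#' @param date A `Date` (vectorised).
#' @param lat,lon Decimal degrees.
#' @return A tibble with columns `date`, `night_end`, `golden_hour_end`,
#'   `sunset`, `night_start` (POSIXct UTC, `NA` when undefined).
#' @export
solar_event_times <- function(date, lat, lon) {
  date <- as.Date(date)
  n <- max(length(date), length(lat), length(lon))
  date <- rep_len(date, n); lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  rows <- purrr::pmap(list(date, lat, lon), solar_events_one)
  out <- bind_rows(rows)
  out$date <- date
  select(out, "date", "night_end", "golden_hour_end", "sunset", "night_start")
}

solar_events_one <- function(date, lat, lon) {
  # local mean solar day: UTC midnight shifted by -lon/15 hours
  t0 <- as.numeric(utc_time(format(date))) - lon / 15 * 3600
  tibble(
    night_end = find_crossing(t0, lat, lon, NIGHT_ALT, ascending = TRUE),
    golden_hour_end = find_crossing(t0, lat, lon, GOLDEN_ALT, ascending = TRUE),
    sunset = find_crossing(t0, lat, lon, SUNSET_ALT, ascending = FALSE),
    night_start = find_crossing(t0, lat, lon, NIGHT_ALT, ascending = FALSE)
  )
}

find_crossing <- function(t0, lat, lon, thresh, ascending) {
  grid <- seq(t0, t0 + 86400, by = 120)
  f <- solar_altitude(grid, lat, lon) - thresh
  n <- length(grid)
  dir_ok <- if (ascending) f[-1] > f[-n] else f[-1] < f[-n]
  sign_ok <- if (ascending) f[-n] <= 0 & f[-1] >= 0 else f[-n] >= 0 & f[-1] <= 0
  idx <- which(dir_ok & sign_ok & f[-n] != f[-1])
  if (length(idx) == 0) return(as_utc(as.POSIXct(NA)))
  i <- idx[1]
  root <- stats::uniroot(function(t) solar_altitude(t, lat, lon) - thresh,
                         lower = grid[i], upper = grid[i + 1], tol = 0.5)$root
  as_utc(as.POSIXct(root, origin = "1970-01-01"))
}

#' Classify an instant into dawn, day, dusk or night
#'
#' Instantaneous diel classification from solar altitude and the ascending
#' flag, equivalent at the study latitudes to interval membership between the
#' events of [solar_event_times()]: night while the sun is below -18 degrees;
#' dawn while ascending between -18 and +6 degrees (end of night to end of the
#' morning golden hour); day above +6 degrees or while descending above
#' -0.833 degrees (until sunset); dusk while descending between -0.833 and
#' -18 degrees (sunset to start of night). The rule set is total, so every
#' instant at every latitude receives exactly one label; on high-latitude
#' degenerate days it degrades to an altitude-only rule.
#'
#' @inheritParams solar_position
#' @return A factor with levels `dawn`, `day`, `dusk`, `night`.
#' @export
classify_period <- function(time, lat, lon) {
  sp <- solar_position(time, lat, lon)
  out <- character(nrow(sp))
  night <- sp$altitude < NIGHT_ALT
  dawn <- !night & sp$ascending & sp$altitude < GOLDEN_ALT
  day <- sp$altitude >= GOLDEN_ALT | (!sp$ascending & sp$altitude > SUNSET_ALT)
  out[night] <- "night"
  out[dawn] <- "dawn"
  out[!night & !dawn & day] <- "day"
  out[out == ""] <- "dusk"
  period_factor(out)
}

#' Annotate detections with the diel period
#'
#' Adds a `period` column (dawn/day/dusk/night) to a detection table, each
#' detection classified by the solar geometry at its own station's
#' coordinates.
#'
#' @param detections Detection tibble.
#' @param stations Station tibble with `station_id`, `latitude`, `longitude`.
#' @return The detections with a `period` factor column appended.
#' @export
annotate_periods <- function(detections, stations) {
  check_columns(stations, c("station_id", "latitude", "longitude"), "station table")
  idx <- match(detections$station_id, stations$station_id)
  if (anyNA(idx)) {
    abort("detections reference stations absent from the station table",
          class = "reefnet_unknown_station")
  }
  mutate(detections,
         period = classify_period(.data$timestamp,
                                  stations$latitude[idx],
                                  stations$longitude[idx]))
}
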