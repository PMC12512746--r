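#' Default agent configurations for the synthetic study
#'
#' Builds the simulator's default cast: reef sharks homed just outside the
#' passage mouths with moderate ranging, sex-specific behaviour (females get
#' a larger step scale and a per-day probability of an inter-atoll excursion
#' when more than one atoll exists) and diel activity reduced around dawn;
#' and lagoon-resident mesopredatory fish (red bass type) with small steps,
#' strong site fidelity and no excursions.
#'
#' @param reef A list with `scene` and `stations` from [build_reef_scene()].
#' @param n_sharks,n_fish Number of shark and fish agents.
#' @param shark_step_sd_m,fish_step_sd_m Per-step (60 s) step-length scale.
#' @param female_step_factor Multiplier on female shark step scale.
#' @param p_excursion_f,p_excursion_m Per-day inter-atoll excursion
#'   probability by sex (applied only when a second atoll exists).
#' @param diel Named activity multipliers for dawn/day/dusk/night.
#' @param home_angle_spread Half-width (radians) of the angular scatter of
#'   shark home centres about the passage bearing; larger values place homes
#'   farther from the passage along the reef.
#' @param seed Integer seed.
#' @return An agent tibble, one row per animal, consumable by
#'   [simulate_tracks()].
#' @export
default_agents <- function(reef, n_sharks = 10L, n_fish = 6L,
                           shark_step_sd_m = 26, fish_step_sd_m = 10,
                           female_step_factor = 1.6,
                           p_excursion_f = 0.08, p_excursion_m = 0.01,
                           diel = c(dawn = 0.4, day = 1.2, dusk = 0.8, night = 1),
                           home_angle_spread = 0.25, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  scene <- reef$scene
  p1 <- scene$passages[1, ]
  second_atoll <- if (nrow(scene$atolls) > 1) scene$atolls$atoll[2] else NA_character_
  crest_o <- scene$atolls$crest_outer_m[1]
  a1 <- scene$atolls[1, ]

  sharks <- if (n_sharks > 0) {
    sex <- rep(c("F", "M"), length.out = n_sharks)
    ang <- p1$angle + runif(n_sharks, -home_angle_spread, home_angle_spread)
    rad <- crest_o + runif(n_sharks, 250, 700)
    tibble(
      tag_id = sprintf("GRS%02d", seq_len(n_sharks)),
      species = "grey_reef_shark", sex = sex,
      total_length_cm = round(rnorm(n_sharks, 146, 19), 1),
      home_x = a1$cx + rad * cos(ang), home_y = a1$cy + rad * sin(ang),
      attraction = 0.012,
      step_sd_m = shark_step_sd_m * ifelse(sex == "F", female_step_factor, 1),
      diel_dawn = diel[["dawn"]], diel_day = diel[["day"]],
      diel_dusk = diel[["dusk"]], diel_night = diel[["night"]],
      p_excursion = ifelse(sex == "F", p_excursion_f, p_excursion_m) *
        !is.na(second_atoll),
      excursion_atoll = second_atoll
    )
  } else NULL

  fish <- if (n_fish > 0) {
    ang <- p1$angle + runif(n_fish, -0.5, 0.5)
    rad <- runif(n_fish, 0.45, 0.8) * a1$lagoon_radius_m
    tibble(
      tag_id = sprintf("RB%02d", seq_len(n_fish)),
      species = "red_bass", sex = "U",
      total_length_cm = round(rnorm(n_fish, 59, 5), 1),
      home_x = a1$cx + rad * cos(ang), home_y = a1$cy + rad * sin(ang),
      attraction = 0.02, step_sd_m = fish_step_sd_m,
      diel_dawn = 0.5, diel_day = 1.2, diel_dusk = 0.5, diel_night = 1,
      p_excursion = 0, excursion_atoll = NA_character_
    )
  } else NULL
  bind_rows(sharks, fish)
}

#' Simulate animal tracks over a reef scene
#'
#' Each agent performs a biased correlated random walk: directional
#' persistence plus Gaussian steps whose scale is the agent's `step_sd_m`
#' times its diel activity multiplier for the current period, plus attraction
#' toward the agent's home centre, with the reef crest acting as a reflecting
#' barrier. On excursion days (drawn per day with probability `p_excursion`)
#' the home centre switches to the target atoll's centre for that day, then
#' returns. The diel period per step is classified once at the scene's
#' geographic anchor (solar geometry varies negligibly across an atoll).
#'
#' @param reef A list with `scene` and `stations` from [build_reef_scene()].
#' @param agents Agent tibble (see [default_agents()]).
#' @param duration_days Track length in days (default 30).
#' @param dt_s Positional time step in seconds (default 60).
#' @param start Start instant (POSIXct UTC or string).
#' @param persistence Velocity-persistence coefficient in [0, 1).
#' @param max_pull_m Cap on the per-step homing displacement (metres).
#' @param seed Integer seed.
#' @return A tibble `tag_id`, `time`, `x_m`, `y_m`.
#' @export
simulate_tracks <- function(reef, agents, duration_days = 30, dt_s = 60,
                            start = "2013-05-01 00:00:00", persistence = 0.6,
                            max_pull_m = 250, seed = 1L) {
  stopifnot(duration_days > 0)
  scene <- reef$scene
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  n_steps <- as.integer(round(duration_days * 86400 / dt_s))
  steps_per_day <- as.integer(round(86400 / dt_s))
  times <- utc_time(start) + dt_s * (seq_len(n_steps) - 1)
  ref_lat <- scene$origin_lonlat[2]
  ref_lon <- scene$origin_lonlat[1]
  period <- as.character(classify_period(times, ref_lat, ref_lon))
  n_days <- ceiling(n_steps / steps_per_day)
  day_idx <- rep(seq_len(n_days), each = steps_per_day)[seq_len(n_steps)]
  barrier <- matrix(as.integer(scene$crest_mask), nrow(scene$crest_mask))

  tracks <- purrr::map(seq_len(nrow(agents)), function(k) {
    ag <- agents[k, ]
    mult <- c(dawn = ag$diel_dawn, day = ag$diel_day,
              dusk = ag$diel_dusk, night = ag$diel_night)
    step_sd <- ag$step_sd_m * unname(mult[period])
    hx <- rep(ag$home_x, n_steps)
    hy <- rep(ag$home_y, n_steps)
    if (!is.na(ag$excursion_atoll) && ag$p_excursion > 0) {
      exc_day <- rbinom(n_days, 1, ag$p_excursion) == 1
      tgt <- filter(scene$atolls, .data$atoll == ag$excursion_atoll)
      ps <- filter(scene$passages, .data$atoll == ag$excursion_atoll)
      if (nrow(tgt) == 1 && any(exc_day)) {
        # excursions head for the destination atoll's passage mouth (the
        # crest ring would block a run at the lagoon centre)
        if (nrow(ps) > 0) {
          r_out <- tgt$crest_outer_m[1] + 300
          ex <- tgt$cx + r_out * cos(ps$angle[1])
          ey <- tgt$cy + r_out * sin(ps$angle[1])
        } else {
          ex <- tgt$cx; ey <- tgt$cy
        }
        on_exc <- exc_day[day_idx]
        hx[on_exc] <- ex
        hy[on_exc] <- ey
      }
    }
    xy <- bcrw_walk(ag$home_x, ag$home_y, hx, hy, step_sd,
                    ag$attraction, persistence, max_pull_m, barrier,
                    scene$cell_size_m, scene$origin[1], scene$origin[2])
    tibble(tag_id = ag$tag_id, time = times, x_m = xy[, 1], y_m = xy[, 2])
  })
  bind_rows(tracks)
}

#' Simulate acoustic detections of simulated tracks
#'
#' Transmitters ping at jittered intervals; each ping is detected
#' independently by each receiver with logistic probability
#' `p(d) = 1 / (1 + exp((d - d50_m) / slope_m))` of the ping-receiver
#' distance, so detection probability is 0.5 at the receiver range estimate
#' `d50_m` (default 300 m) and falls off with steepness `slope_m`. Detected
#' pings become detection records; QC flags are drawn from `qc_probs` to
#' exercise the quality filter (flag 1 = valid).
#'
#' @param tracks Track tibble from [simulate_tracks()].
#' @param stations Station table with planar `x_m`, `y_m`.
#' @param ping_interval_s Mean transmitter interval (default 90).
#' @param ping_jitter_s Uniform jitter half-width on each interval.
#' @param d50_m Distance of 50% detection probability (default 300).
#' @param slope_m Logistic steepness (default 50).
#' @param qc_probs Probabilities of QC flags 1-4 per detection.
#' @param seed Integer seed.
#' @return A detection tibble: `tag_id`, `station_id`, `timestamp` (UTC,
#'   second resolution), `qc_flag`.
#' @export
simulate_detections <- function(tracks, stations, ping_interval_s = 90,
                                ping_jitter_s = 30, d50_m = 300, slope_m = 50,
                                qc_probs = c(0.96, 0.02, 0.015, 0.005),
                                seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  qc_probs <- qc_probs / sum(qc_probs)
  sx <- stations$x_m; sy <- stations$y_m
  res <- tracks %>%
    dplyr::group_split(.data$tag_id) %>%
    purrr::map(function(tr) {
      t0 <- as.numeric(tr$time[1])
      t_end <- as.numeric(tr$time[nrow(tr)])
      dt <- as.numeric(tr$time[2]) - t0
      n_max <- ceiling((t_end - t0) / max(ping_interval_s - ping_jitter_s, 1)) + 1
      gaps <- ping_interval_s + runif(n_max, -ping_jitter_s, ping_jitter_s)
      pt <- t0 + cumsum(gaps)
      pt <- pt[pt <= t_end]
      if (length(pt) == 0) return(NULL)
      idx <- pmin(floor((pt - t0) / dt) + 1, nrow(tr))
      px <- tr$x_m[idx]; py <- tr$y_m[idx]
      d <- sqrt(outer(px, sx, "-")^2 + outer(py, sy, "-")^2)
      p <- plogis((d50_m - d) / slope_m)
      hit <- matrix(runif(length(p)), nrow(p)) < p
      ij <- which(hit, arr.ind = TRUE)
      if (nrow(ij) == 0) return(NULL)
      tibble(
        tag_id = tr$tag_id[1],
        station_id = stations$station_id[ij[, 2]],
        timestamp = as_utc(as.POSIXct(round(pt[ij[, 1]]), origin = "1970-01-01"))
      ) %>% arrange(.data$timestamp, .data$station_id)
    })
  det <- bind_rows(res)
  if (nrow(det) == 0) {
    return(tibble(tag_id = character(), station_id = character(),
                  timestamp = as_utc(as.POSIXct(character())),
                  qc_flag = integer()))
  }
  det$qc_flag <- sample(1:4, nrow(det), replace = TRUE, prob = qc_probs)
  arrange(det, .data$tag_id, .data$timestamp)
}

#' Simulate a complete synthetic telemetry study
#'
#' One-call generator of everything the pipeline consumes: reef scene,
#' receiver array, agents, tracks, detections and the tag-deployment table.
#' All randomness flows from the single `seed`, fanned out to independent
#' substreams (scene, agents, tracks, detections) so each stage is
#' individually reproducible.
#'
#' @param seed Top-level integer seed.
#' @param duration_days,dt_s Track length and resolution.
#' @param scene_args,agent_args Named lists of overrides passed to
#'   [build_reef_scene()] and [default_agents()].
#' @param detection_args Named list of overrides for
#'   [simulate_detections()].
#' @param start Study start instant.
#' @param keep_tracks Keep the (large) track tibble in the result.
#' @return A list: `scene`, `stations`, `agents`, `tags`, `detections` (and
#'   `tracks` if kept).
#' @export
simulate_telemetry <- function(seed = 1L, duration_days = 30, dt_s = 60,
                               scene_args = list(), agent_args = list(),
                               detection_args = list(),
                               start = "2013-05-01 00:00:00",
                               keep_tracks = FALSE) {
  seeds <- substream_seeds(seed, 4L)
  reef <- do.call(build_reef_scene, c(scene_args, list(seed = seeds[1])))
  agents <- do.call(default_agents, c(list(reef = reef), agent_args,
                                      list(seed = seeds[2])))
  tracks <- simulate_tracks(reef, agents, duration_days, dt_s, start,
                            seed = seeds[3])
  detections <- do.call(simulate_detections,
                        c(list(tracks = tracks, stations = reef$stations),
                          detection_args, list(seed = seeds[4])))
  tags <- agents %>%
    mutate(deploy_datetime = utc_time(start), deploy_station = NA_character_) %>%
    select("tag_id", "species", "sex", "total_length_cm",
           "deploy_datetime", "deploy_station")
  out <- list(scene = reef$scene, stations = reef$stations, agents = agents,
              tags = tags, detections = detections)
  if (keep_tracks) out$tracks <- tracks
  out
}
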