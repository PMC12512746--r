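#' Extract movement events from consecutive detections
#'
#' A movement event is an ordered pair of consecutive detections of one
#' individual: from the station of the earlier detection to the station of
#' the later one. Consecutive detections at the same station form self-loops
#' (residency), which are kept and flagged. A tag with n detections yields
#' exactly n - 1 chainable events. The event's diel period is taken from the
#' departing detection by default (the movement is initiated then).
#'
#' @param detections Filtered, deduplicated detection tibble sorted by
#'   (`tag_id`, `timestamp`); a `period` column is carried through if present.
#' @param period_from Assign each event the period of its `"depart"`
#'   (default) or `"arrive"` detection.
#' @return A tibble of movement events: `tag_id`, `from_station`,
#'   `to_station`, `depart_time`, `arrive_time`, `dt_h` (hours, > 0),
#'   `period` (if available) and `is_self_loop`.
#' @export
extract_movement_events <- function(detections, period_from = c("depart", "arrive")) {
  period_from <- match.arg(period_from)
  has_period <- "period" %in% names(detections)
  # a ping heard by two receivers in the same second has no movement order:
  # keep one detection per (tag, instant), first station id as tie-break
  ev <- detections %>%
    arrange(.data$tag_id, .data$timestamp, .data$station_id) %>%
    distinct(.data$tag_id, .data$timestamp, .keep_all = TRUE) %>%
    group_by(.data$tag_id) %>%
    mutate(
      from_station = .data$station_id,
      to_station = lead(.data$station_id),
      depart_time = .data$timestamp,
      arrive_time = lead(.data$timestamp),
      .period_arrive = if (has_period) lead(.data$period) else NA
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$to_station))
  out <- tibble(
    tag_id = ev$tag_id,
    from_station = ev$from_station,
    to_station = ev$to_station,
    depart_time = ev$depart_time,
    arrive_time = ev$arrive_time,
    dt_h = as.numeric(difftime(ev$arrive_time, ev$depart_time, units = "hours")),
    is_self_loop = ev$from_station == ev$to_station
  )
  if (has_period) {
    out$period <- period_factor(
      if (period_from == "depart") as.character(ev$period) else as.character(ev$.period_arrive)
    )
  }
  # per-tag constants ride along when present
  for (col in intersect(c("species", "sex"), names(detections))) {
    out[[col]] <- ev[[col]]
  }
  out
}

#' Log-inverse-time edge weight
#'
#' The weight of an edge is the sum over its contributing movement events of
#' the log of the inverse inter-detection interval, so that movements with
#' shorter times between detections contribute greater strength. Intervals
#' are floored at `dt_floor_h` (default 5 minutes, the deduplication
#' resolution) so near-simultaneous cross-station detections cannot produce
#' unbounded weights. Intervals are in hours and the log is natural by
#' default; both only rescale weights monotonically.
#'
#' @param intervals_h Positive inter-detection intervals in hours.
#' @param dt_floor_h Lower floor applied to each interval (hours).
#' @param log_base Base of the logarithm (default `exp(1)`).
#' @return A single numeric weight, `sum(log(1 / pmax(dt, floor)))`.
#' @export
edge_weight <- function(intervals_h, dt_floor_h = 1 / 12, log_base = exp(1)) {
  if (length(intervals_h) == 0) return(0)
  if (any(intervals_h <= 0)) {
    abort("movement intervals must be strictly positive")
  }
  sum(log(1 / pmax(intervals_h, dt_floor_h), base = log_base))
}

#' Build one directed weighted movement network
#'
#' Aggregates movement events by ordered station pair into a directed,
#' weighted network. Directionality is preserved (A to B is distinct from B
#' to A). Self-loops are kept as node-level residency bookkeeping, separate
#' from the between-station edges. Events can be filtered to a stratum by
#' species, sex, period or individual before aggregation.
#'
#' @param events Movement-event tibble from [extract_movement_events()]. For
#'   species/sex filters the events must carry `species`/`sex` columns.
#' @param nodes Optional character vector of station ids detected in the
#'   stratum; defaults to the stations appearing in the retained events.
#' @param species,sex,period,tag_id Optional stratum filters.
#' @param stations Optional station tibble; matching attributes (latitude,
#'   longitude, atoll, reef_system) are attached to the nodes.
#' @param dt_floor_h,log_base Passed to [edge_weight()].
#' @return A `movement_network` object: a list with `stratum` (named list),
#'   `nodes`, `edges` (`from`, `to`, `event_count`, `weight`) and
#'   `self_loops` tibbles.
#' @export
build_network <- function(events, nodes = NULL, species = NULL, sex = NULL,
                          period = NULL, tag_id = NULL, stations = NULL,
                          dt_floor_h = 1 / 12, log_base = exp(1)) {
  stratum <- list(
    species = species %||% "all", sex = sex %||% "all",
    period = period %||% "all", tag_id = tag_id %||% "all"
  )
  if (!is.null(species)) events <- filter(events, .data$species %in% !!species)
  if (!is.null(sex)) events <- filter(events, .data$sex %in% !!sex)
  if (!is.null(period)) events <- filter(events, .data$period %in% !!period)
  if (!is.null(tag_id)) events <- filter(events, .data$tag_id %in% !!tag_id)

  if (is.null(nodes)) {
    nodes <- sort(unique(c(events$from_station, events$to_station)))
  } else {
    nodes <- sort(unique(nodes))
  }

  aggregate_pairs <- function(ev) {
    if (nrow(ev) == 0) {
      return(tibble(from = character(), to = character(),
                    event_count = integer(), weight = numeric()))
    }
    ev %>%
      group_by(.data$from_station, .data$to_station) %>%
      summarise(event_count = dplyr::n(),
                weight = edge_weight(.data$dt_h, dt_floor_h, log_base),
                .groups = "drop") %>%
      rename(from = "from_station", to = "to_station") %>%
      arrange(.data$from, .data$to)
  }

  edges <- aggregate_pairs(filter(events, !.data$is_self_loop))
  loops <- aggregate_pairs(filter(events, .data$is_self_loop)) %>%
    select(station_id = "from", "event_count", "weight")

  node_tbl <- tibble(station_id = nodes)
  if (!is.null(stations)) {
    node_tbl <- left_join(
      node_tbl,
      select(stations, any_of(c("station_id", "latitude", "longitude",
                                "reef_system", "atoll", "x_m", "y_m"))),
      by = "station_id"
    )
  }
  structure(
    list(stratum = stratum, nodes = node_tbl, edges = edges, self_loops = loops),
    class = "movement_network"
  )
}

#' @export
print.movement_network <- function(x, ...) {
  s <- summarize_network(x)
  lab <- paste(
    vapply(names(x$stratum), function(k) paste0(k, "=", x$stratum[[k]]), ""),
    collapse = ", "
  )
  cat(sprintf("<movement_network> %s\n", lab))
  cat(sprintf("  order %d, size %d, components %d, self-loop events %d\n",
              s$order, s$size, s$n_components, sum(x$self_loops$event_count)))
  invisible(x)
}

#' Total number of movement events in a network (self-loops included)
#' @param net A `movement_network`.
#' @return Integer event count.
#' @export
network_event_count <- function(net) {
  sum(net$edges$event_count) + sum(net$self_loops$event_count)
}

#' Build every stratified movement network
#'
#' For each species and reef system, builds the full network, the four
#' diel-period networks (dawn, day, dusk, night), per-sex networks (sexes F
#' and M only; individuals of unknown sex are included in the full, period
#' and individual networks but excluded from sex strata), and one network per
#' individual, retaining only individual networks spanning at least
#' `min_individual_nodes` receivers.
#'
#' Period-stratum node sets are the stations with at least one detection
#' classified in that period; other strata use the stations detected for the
#' stratum's tags.
#'
#' @param detections Filtered detections with a `period` column (see
#'   [annotate_periods()]).
#' @param tags Tag table (`tag_id`, `species`, `sex`).
#' @param stations Optional station tibble (attaches node coordinates and a
#'   `reef_system` stratification level).
#' @param min_individual_nodes Node-count rule for individual networks
#'   (default 3).
#' @inheritParams build_network
#' @inheritParams extract_movement_events
#' @return A tibble with columns `species`, `reef_system`, `stratum_type`
#'   (full/period/sex/individual), `stratum_value`, `order`, `size`, and a
#'   `network` list-column of `movement_network` objects.
#' @export
build_stratified_networks <- function(detections, tags, stations = NULL,
                                      min_individual_nodes = 3L,
                                      dt_floor_h = 1 / 12, log_base = exp(1),
                                      period_from = c("depart", "arrive")) {
  period_from <- match.arg(period_from)
  det <- detections
  if (!"species" %in% names(det) || !"sex" %in% names(det)) {
    det <- det %>%
      select(-any_of(c("species", "sex"))) %>%
      left_join(select(tags, "tag_id", "species", "sex"), by = "tag_id")
    det$species[is.na(det$species)] <- "unknown"
    det$sex[is.na(det$sex)] <- "U"
  }
  if (!is.null(stations) && "reef_system" %in% names(stations)) {
    det <- left_join(det, select(stations, "station_id", "reef_system"),
                     by = "station_id")
  } else {
    det$reef_system <- "all"
  }

  combos <- det %>%
    filter(.data$species != "unknown") %>%
    distinct(.data$species, .data$reef_system)
  if (nrow(combos) == 0) {
    return(tibble(species = character(), reef_system = character(),
                  stratum_type = character(), stratum_value = character(),
                  order = integer(), size = integer(), network = list()))
  }

  res <- purrr::pmap(combos, function(species, reef_system) {
    d <- filter(det, .data$species == !!species, .data$reef_system == !!reef_system)
    ev <- extract_movement_events(d, period_from)
    rows <- list()
    add <- function(type, value, net) {
      tibble(species = species, reef_system = reef_system,
             stratum_type = type, stratum_value = value,
             order = nrow(net$nodes), size = nrow(net$edges),
             network = list(net))
    }
    full <- build_network(ev, nodes = unique(d$station_id), species = species,
                          stations = stations, dt_floor_h = dt_floor_h,
                          log_base = log_base)
    rows <- c(rows, list(add("full", "all", full)))
    for (p in PERIOD_LEVELS) {
      np <- unique(d$station_id[as.character(d$period) == p])
      rows <- c(rows, list(add("period", p, build_network(
        ev, nodes = np, species = species, period = p, stations = stations,
        dt_floor_h = dt_floor_h, log_base = log_base
      ))))
    }
    sexes <- intersect(c("F", "M"), unique(d$sex))
    for (s in sexes) {
      tags_s <- unique(d$tag_id[d$sex == s])
      ns <- unique(d$station_id[d$tag_id %in% tags_s])
      rows <- c(rows, list(add("sex", s, build_network(
        ev, nodes = ns, species = species, sex = s, stations = stations,
        dt_floor_h = dt_floor_h, log_base = log_base
      ))))
    }
    for (tg in sort(unique(d$tag_id))) {
      ni <- unique(d$station_id[d$tag_id == tg])
      net <- build_network(ev, nodes = ni, species = species, tag_id = tg,
                           stations = stations, dt_floor_h = dt_floor_h,
                           log_base = log_base)
      if (nrow(net$nodes) >= min_individual_nodes) {
        rows <- c(rows, list(add("individual", tg, net)))
      }
    }
    bind_rows(rows)
  })
  bind_rows(res)
}
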