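test_that("movement events are the n-1 consecutive pairs, self-loops flagged", {
  det <- make_detections("T1", c("R1", "R1", "R2"), c(0, 600, 1800))
  ev <- extract_movement_events(det)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$from_station, c("R1", "R1"))
  expect_equal(ev$to_station, c("R1", "R2"))
  expect_equal(ev$is_self_loop, c(TRUE, FALSE))
  expect_equal(ev$dt_h, c(600, 1200) / 3600)

  # single detection: no events
  expect_equal(nrow(extract_movement_events(make_detections("T1", "R1", 0))), 0)

  # n = 6 -> 5 chainable events
  det6 <- make_detections("T1", paste0("R", c(1, 2, 1, 3, 2, 1)), (0:5) * 900)
  ev6 <- extract_movement_events(det6)
  expect_equal(nrow(ev6), 5)
  expect_equal(ev6$arrive_time[-5], ev6$depart_time[-1])
})

test_that("edge weight is the summed log-inverse interval with a floor", {
  expect_equal(edge_weight(1), 0)
  expect_equal(edge_weight(c(0.5, 0.5)), 2 * log(2))
  expect_equal(edge_weight(0.01), log(12))          # floored at 5 min
  expect_equal(edge_weight(2, log_base = 2), -1)    # base is configurable
  expect_error(edge_weight(c(1, 0)), "positive")
  expect_error(edge_weight(-1), "positive")
  # monotonically decreasing in each interval above the floor
  expect_true(edge_weight(0.3) > edge_weight(0.6))
})

test_that("networks aggregate ordered pairs with direction preserved", {
  det <- make_detections("T1", c("A", "B", "A", "B", "A"), (0:4) * 3600)
  ev <- extract_movement_events(det)
  net <- build_network(ev)
  expect_equal(nrow(net$edges), 2)
  ab <- net$edges[net$edges$from == "A", ]
  ba <- net$edges[net$edges$from == "B", ]
  expect_equal(ab$event_count, 2L)
  expect_equal(ba$event_count, 2L)
  # aggregated weight equals edge_weight of the pooled interval list
  expect_equal(ab$weight, edge_weight(c(1, 1)))

  # self-loops only: order 1, size 0
  loop <- build_network(extract_movement_events(
    make_detections("T1", c("A", "A", "A"), c(0, 3600, 7200))))
  expect_equal(nrow(loop$nodes), 1)
  expect_equal(nrow(loop$edges), 0)
  expect_equal(loop$self_loops$event_count, 2L)

  # stratum with no events: empty network, not an error
  det$period <- period_factor("day")
  ev_p <- extract_movement_events(det)
  empty <- build_network(ev_p, period = "dawn")
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("stratified networks follow the sex, period and 3-node rules", {
  day <- 86400
  mk <- function(tag, stations) {
    d <- make_detections(tag, stations, seq_along(stations) * 3600)
    d
  }
  det <- dplyr::bind_rows(
    mk("F1", c("A", "B", "C", "A", "B")),
    mk("M1", c("A", "C", "B", "C")),
    mk("U1", c("B", "A", "C", "B")),
    mk("S2", c("A", "B", "A"))     # two-station individual
  )
  tags <- tibble::tibble(
    tag_id = c("F1", "M1", "U1", "S2"),
    species = "grey_reef_shark",
    sex = c("F", "M", "U", "F")
  )
  st <- tibble::tibble(station_id = c("A", "B", "C"),
                       latitude = -14, longitude = 121.8,
                       reef_system = "R", atoll = "A1")
  det <- dplyr::left_join(det, tags[, c("tag_id", "species", "sex")], by = "tag_id")
  det <- annotate_periods(det, st)
  nets <- build_stratified_networks(det, tags, st)

  # exactly two sex networks (F, M); U excluded from sex strata
  expect_equal(sort(nets$stratum_value[nets$stratum_type == "sex"]), c("F", "M"))
  # four period networks always
  expect_equal(sort(nets$stratum_value[nets$stratum_type == "period"]),
               sort(PERIOD_LEVELS_TEST))
  # S2 visits 2 stations: dropped from the individual collection
  ind <- nets$stratum_value[nets$stratum_type == "individual"]
  expect_true(all(c("F1", "M1", "U1") %in% ind))
  expect_false("S2" %in% ind)

  # period partition: the four period networks' events partition the full set
  full_ev <- network_event_count(nets$network[[which(nets$stratum_type == "full")]])
  per_ev <- sum(vapply(nets$network[nets$stratum_type == "period"],
                       network_event_count, integer(1)))
  expect_equal(per_ev, full_ev)
  # U's events are in the full network but neither sex network
  sex_ev <- sum(vapply(nets$network[nets$stratum_type == "sex"],
                       network_event_count, integer(1)))
  expect_equal(full_ev - sex_ev, 3L)  # U1 contributes 4 detections -> 3 events
})

test_that("rebuilding from shuffled detections yields identical networks", {
  sim <- small_sim()
  ann <- sim$annotated
  set.seed(99)
  shuffled <- ann[sample.int(nrow(ann)), ]
  n1 <- build_stratified_networks(ann, sim$sim$tags, sim$sim$stations)
  n2 <- build_stratified_networks(shuffled, sim$sim$tags, sim$sim$stations)
  expect_equal(n1$stratum_value, n2$stratum_value)
  for (k in seq_len(nrow(n1))) {
    expect_equal(n1$network[[k]]$edges, n2$network[[k]]$edges)
    expect_equal(n1$network[[k]]$self_loops, n2$network[[k]]$self_loops)
  }
})

test_that("event conservation holds on simulated data", {
  sim <- small_sim()
  ann <- sim$annotated
  nets <- build_stratified_networks(ann, sim$sim$tags, sim$sim$stations)
  full_ev <- sum(vapply(nets$network[nets$stratum_type == "full"],
                        network_event_count, integer(1)))
  n_minus_1 <- ann %>%
    dplyr::distinct(tag_id, timestamp) %>%
    dplyr::count(tag_id) %>%
    dplyr::summarise(v = sum(n - 1)) %>%
    dplyr::pull(v)
  expect_equal(full_ev, n_minus_1)
})
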